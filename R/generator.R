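# Seeded generator of heterogeneous arteriolar trees.
#
# The construction mirrors how arteriolar branches are organised in vivo:
# a vessel of a given order is a chain of segments that sheds side branches
# of deeper order along its course and ends in a bifurcation. Pathways
# therefore traverse several same-order segments before stepping down in
# diameter, which produces the non-uniform distribution of orders (and of
# path resistances, hence terminal flows) that drives downstream
# heterogeneity.

#' Generator configuration for synthetic arteriolar trees
#'
#' @param seed integer seed; identical configurations produce bit-identical
#'   networks.
#' @param n_terminals number of terminal arterioles (>= 1).
#' @param max_order deepest branching order (terminal order), 4 or 5.
#' @param order_diameters map order -> diameter in um, strictly decreasing.
#'   Default `c(117, 73, 44, 32, 22)` for orders 1..5.
#' @param order_length_mean per-order mean segment length, um.
#' @param order_length_cv per-order coefficient of variation of segment
#'   length (lognormal draws truncated to \[0.2, 5\] times the mean).
#' @param asymmetry in \[0, 1\]: 0 gives near-symmetric allocation of
#'   terminals among sibling subtrees, values near 1 give strongly skewed
#'   allocations (right-skewed capillary-count distributions downstream).
#' @param order_skip_prob probability that a side branch steps down two
#'   orders at once, yielding pathways that traverse 4 rather than 5
#'   distinct orders.
#' @param domain_extent 3-vector, um: bounding box the embedded tree must
#'   fit in (generation retries with fresh draws, then errors).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_terminals = 60L,
                             max_order = 5L,
                             order_diameters = c(`1` = 117, `2` = 73, `3` = 44,
                                                 `4` = 32, `5` = 22),
                             order_length_mean = c(550, 480, 420, 400, 650),
                             order_length_cv = c(0.35, 0.35, 0.35, 0.35, 0.45),
                             asymmetry = 0.6,
                             order_skip_prob = 0.2,
                             domain_extent = c(40000, 40000, 400)) {
  stopifnot(n_terminals >= 1, max_order %in% c(4L, 5L),
            asymmetry >= 0, asymmetry <= 1,
            length(order_diameters) >= max_order,
            all(diff(order_diameters) < 0))
  if (length(order_length_cv) == 1)
    order_length_cv <- rep(order_length_cv, length(order_length_mean))
  structure(list(seed = as.integer(seed), n_terminals = as.integer(n_terminals),
                 max_order = as.integer(max_order),
                 order_diameters = order_diameters,
                 order_length_mean = order_length_mean,
                 order_length_cv = order_length_cv,
                 asymmetry = asymmetry,
                 order_skip_prob = order_skip_prob,
                 domain_extent = domain_extent),
            class = "generator_config")
}

# run expr with a private, seeded RNG stream, restoring global state after
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rlnorm_trunc <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  pmin(pmax(stats::rlnorm(n, meanlog, sdlog), 0.2 * mean), 5 * mean)
}

#' Generate a heterogeneous arteriolar tree
#'
#' Builds a rooted arteriolar tree with exactly `cfg$n_terminals` terminal
#' arterioles, per-order diameters from `cfg$order_diameters`, per-order
#' lognormal segment lengths, and a quasi-planar 3-D embedding (recursive
#' angular fanning with small z jitter). All segments are oriented
#' root-to-leaf, so solved flows are non-negative.
#'
#' @param cfg a [generator_config()].
#' @return A validated `vascular_network`.
#' @export
#' @examples
#' net <- generate_arteriolar_tree(generator_config(seed = 1, n_terminals = 8))
#' net
generate_arteriolar_tree <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  best <- NULL
  best_clear <- -Inf
  for (attempt in 1:8) {
    net <- with_private_seed(cfg$seed + (attempt - 1L) * 997L,
                             build_tree_once(cfg))
    ext <- apply(net$nodes[, c("x", "y", "z")], 2, function(v) diff(range(v)))
    if (any(ext > cfg$domain_extent)) next
    cl <- min_segment_clearance(net)
    if (cl > best_clear) { best <- net; best_clear <- cl }
    # accept once non-adjacent vessels keep a comfortable margin
    if (cl >= 50) return(net)
  }
  if (is.null(best))
    stop("generation error: tree does not fit domain_extent after 8 attempts ",
         "(extent needed ", paste(round(ext), collapse = " x "), " um)")
  if (best_clear < 25)
    warning(sprintf(
      "generated tree has close vessel contacts (min clearance %.0f um)",
      best_clear))
  best
}

# minimum midpoint-sampled distance between non-adjacent segments (um)
min_segment_clearance <- function(net) {
  sg <- net$segments
  nd <- net$nodes
  a <- as.matrix(nd[match(sg$from, nd$id), c("x", "y", "z")])
  b <- as.matrix(nd[match(sg$to, nd$id), c("x", "y", "z")])
  dmin <- Inf
  for (k in seq_len(nrow(sg))) {
    # sample points along segment k against all other segment axes
    share <- sg$from == sg$from[k] | sg$to == sg$from[k] |
      sg$from == sg$to[k] | sg$to == sg$to[k]
    others <- which(!share)
    if (!length(others)) next
    ao <- a[others, , drop = FALSE]; bo <- b[others, , drop = FALSE]
    ab <- bo - ao
    len2 <- pmax(rowSums(ab^2), 1e-12)
    for (t_s in c(0.1, 0.35, 0.65, 0.9)) {
      p <- a[k, ] + t_s * (b[k, ] - a[k, ])
      tt <- ((p[1] - ao[, 1]) * ab[, 1] + (p[2] - ao[, 2]) * ab[, 2] +
               (p[3] - ao[, 3]) * ab[, 3]) / len2
      tt <- pmin(pmax(tt, 0), 1)
      dd <- (p[1] - (ao[, 1] + tt * ab[, 1]))^2 +
        (p[2] - (ao[, 2] + tt * ab[, 2]))^2 +
        (p[3] - (ao[, 3] + tt * ab[, 3]))^2
      dmin <- min(dmin, sqrt(min(dd)))
    }
  }
  dmin
}

build_tree_once <- function(cfg) {
  env <- new.env()
  env$nodes <- list(list(id = 1L, x = 0, y = 0, z = 0))
  env$segments <- list()
  env$next_node <- 2L
  env$next_seg <- 1L

  env$seg_a <- env$seg_b <- matrix(numeric(0), ncol = 3)

  new_node <- function(x, y, z) {
    id <- env$next_node
    env$nodes[[length(env$nodes) + 1L]] <- list(id = id, x = x, y = y, z = z)
    env$next_node <- id + 1L
    id
  }
  add_segment <- function(from, to, order, length, terminal) {
    env$segments[[length(env$segments) + 1L]] <-
      list(id = env$next_seg, from = from, to = to, order = order,
           diameter = unname(cfg$order_diameters[order]),
           length = length, terminal = terminal)
    env$next_seg <- env$next_seg + 1L
    a <- env$nodes[[from]]; b <- env$nodes[[to]]
    env$seg_a <- rbind(env$seg_a, c(a$x, a$y, a$z))
    env$seg_b <- rbind(env$seg_b, c(b$x, b$y, b$z))
  }
  draw_len <- function(order) {
    rlnorm_trunc(1, cfg$order_length_mean[order], cfg$order_length_cv[order])
  }

  # clearance of a candidate segment p0 -> p1 from all existing segments
  # not incident to p0 (siblings and the continuing parent share p0 and are
  # legitimately close at the junction)
  clearance <- function(p0, p1) {
    ns <- nrow(env$seg_a)
    if (ns == 0) return(Inf)
    incident <- rowSums((env$seg_a - matrix(p0, ns, 3, byrow = TRUE))^2) < 1 |
      rowSums((env$seg_b - matrix(p0, ns, 3, byrow = TRUE))^2) < 1
    keep <- which(!incident)
    if (!length(keep)) return(Inf)
    a <- env$seg_a[keep, , drop = FALSE]
    b <- env$seg_b[keep, , drop = FALSE]
    ab <- b - a
    len2 <- pmax(rowSums(ab^2), 1e-12)
    dmin <- Inf
    for (t_new in c(0.3, 0.55, 0.8, 1)) {
      p <- p0 + t_new * (p1 - p0)
      tt <- ((p[1] - a[, 1]) * ab[, 1] + (p[2] - a[, 2]) * ab[, 2] +
               (p[3] - a[, 3]) * ab[, 3]) / len2
      tt <- pmin(pmax(tt, 0), 1)
      dd <- (p[1] - (a[, 1] + tt * ab[, 1]))^2 +
        (p[2] - (a[, 2] + tt * ab[, 2]))^2 +
        (p[3] - (a[, 3] + tt * ab[, 3]))^2
      dmin <- min(dmin, sqrt(min(dd)))
    }
    dmin
  }

  # place a segment endpoint, re-drawing the direction (bounded retries)
  # until the segment keeps clearance from already-placed vessels
  advance <- function(node_id, theta_draw, len, min_clear = 90) {
    nd <- env$nodes[[node_id]]
    p0 <- c(nd$x, nd$y, nd$z)
    best <- NULL; best_clear <- -Inf
    best_theta <- NA_real_
    for (try in 1:10) {
      theta <- theta_draw()
      phi <- stats::runif(1, -0.03, 0.03)
      p1 <- p0 + len * c(cos(theta) * cos(phi), sin(theta) * cos(phi), sin(phi))
      cl <- clearance(p0, p1)
      if (cl > best_clear) { best <- p1; best_clear <- cl; best_theta <- theta }
      if (cl >= min_clear) break
    }
    list(id = new_node(best[1], best[2], best[3]), theta = best_theta)
  }

  alpha <- 10^(1 - 2 * cfg$asymmetry)  # Dirichlet concentration for splits

  split_terminals <- function(n, c) {
    if (c == 1) return(n)
    w <- stats::rgamma(c, shape = alpha)
    w <- w / sum(w)
    alloc <- pmax(1L, floor(w * n))
    # distribute the remainder (or claw back excess) by weight order
    while (sum(alloc) < n) {
      i <- which.max(w * n - alloc)
      alloc[i] <- alloc[i] + 1L
    }
    while (sum(alloc) > n) {
      i <- order(alloc, decreasing = TRUE)[1]
      if (alloc[i] > 1L) alloc[i] <- alloc[i] - 1L
    }
    alloc
  }

  build_vessel <- function(order, n_term, start_node, theta) {
    if (order == cfg$max_order) {
      # terminal arteriole: single leaf segment (n_term is 1 by allocation)
      len <- draw_len(order)
      end <- advance(start_node,
                     function() theta + stats::runif(1, -0.3, 0.3), len)
      add_segment(start_node, end$id, order, len, terminal = TRUE)
      return(invisible(NULL))
    }
    remaining <- cfg$max_order - order
    if (n_term == 1) {
      # single continuation towards the terminal order
      len <- draw_len(order)
      end <- advance(start_node,
                     function() theta + stats::runif(1, -0.2, 0.2), len)
      add_segment(start_node, end$id, order, len, terminal = FALSE)
      nxt <- order + 1L
      if (remaining >= 2 && stats::runif(1) < cfg$order_skip_prob) nxt <- order + 2L
      build_vessel(nxt, 1L, end$id, end$theta)
      return(invisible(NULL))
    }
    r <- n_term^(1 / remaining)  # target branching ratio at this level
    c <- if (remaining == 1) n_term else
      max(2L, min(n_term, stats::rpois(1, r - 1) + 1L + stats::rbinom(1, 1, 0.5)))
    alloc <- split_terminals(n_term, c)
    m <- max(1L, c - 1L)  # chain segments of this vessel
    node <- start_node
    dir <- theta
    side <- sample(c(-1, 1), 1)
    for (j in seq_len(m)) {
      len <- draw_len(order)
      nxt <- advance(node, function() dir + stats::runif(1, -0.15, 0.15), len)
      add_segment(node, nxt$id, order, len, terminal = FALSE)
      node <- nxt$id
      dir <- nxt$theta
      is_last <- j == m
      kids <- if (is_last) seq.int(j, c) else j
      for (k in kids) {
        branch_theta <- if (is_last && k == c)
          dir + side * stats::runif(1, 0.2, 0.5)
        else dir - side * stats::runif(1, 0.7, 1.3)
        side <- -side
        child_order <- order + 1L
        if (alloc[k] == 1L && cfg$max_order - child_order >= 1 &&
            stats::runif(1) < cfg$order_skip_prob)
          child_order <- child_order + 1L
        build_vessel(child_order, alloc[k], node, branch_theta)
      }
    }
    invisible(NULL)
  }

  build_vessel(1L, cfg$n_terminals, 1L, theta = 0)
  nodes <- do.call(rbind.data.frame, env$nodes)
  segments <- do.call(rbind.data.frame, env$segments)
  vascular_network(nodes, segments, inlet_node = 1L,
                   order_diameters = cfg$order_diameters)
}

#' Reference flow through a single capillary
#'
#' Flow in one capillary implied by an assumed capillary diameter, wall
#' shear stress and apparent viscosity, by inverting the Poiseuille shear
#' relation `tau = 32 mu Q / (pi D^3)`. With the defaults (6 um, 15
#' dyn/cm^2, 9.05 cP) this is about 0.211 nl/min.
#'
#' @param diameter capillary diameter, um.
#' @param shear wall shear stress, dyn/cm^2.
#' @param viscosity apparent viscosity, cP.
#' @return Flow in nl/min.
#' @export
capillary_reference_flow <- function(diameter = 6, shear = 15, viscosity = 9.05) {
  d <- um_to_cm(diameter)
  q <- shear * pi * d^3 / (32 * cP_to_poise(viscosity))
  cgs_to_nlmin(q)
}

#' Compartment dimensions for the downstream chains
#'
#' Geometry of the lumped capillary (C), small-venule (SV) and large-venule
#' (LV) compartments attached to each terminal arteriole. Capillary lengths
#' are drawn per chain from a truncated lognormal; venule counts scale with
#' the capillary count. The venule dimensions are model defaults, not
#' literature-reported values.
#'
#' @param capillary_diameter um (default 6).
#' @param cap_length_mean,cap_length_cv lognormal parameters for per-chain
#'   capillary length, um.
#' @param sv_radius,sv_length,sv_ratio small-venule radius/length (um) and
#'   count as a fraction of the capillary count.
#' @param lv_radius,lv_length,lv_ratio large-venule equivalents.
#' @return A `compartment_dims` list.
#' @export
compartment_dims <- function(capillary_diameter = 6,
                             cap_length_mean = 400, cap_length_cv = 0.25,
                             sv_radius = 9, sv_length = 500, sv_ratio = 0.1,
                             lv_radius = 31, lv_length = 2000, lv_ratio = 0.01) {
  structure(as.list(environment()), class = "compartment_dims")
}

#' Attach capillary/venule compartment chains to a solved network
#'
#' One chain is created per terminal arteriole. The capillary count is the
#' terminal flow divided by the single-capillary reference flow, rounded to
#' the nearest integer with a floor of one (a terminal arteriole must feed
#' at least one capillary): `n_C = max(1, round(Q_TA / Q_C))`.
#'
#' @param net a `vascular_network` with solved flows (see [iterate_flow()]).
#' @param q_c single-capillary flow, nl/min; default
#'   [capillary_reference_flow()].
#' @param dims a [compartment_dims()].
#' @param seed seed for the per-chain capillary-length draws.
#' @return A `compartment_chains` data.frame (one row per terminal) with the
#'   chain inflow `q` (nl/min) and inflow pressure `p_in` (mmHg).
#' @export
attach_compartments <- function(net, q_c = capillary_reference_flow(),
                                dims = compartment_dims(), seed = 1L) {
  stopifnot(inherits(net, "vascular_network"), q_c > 0)
  sg <- net$segments
  term <- sg[sg$terminal, ]
  if (anyNA(term$flow)) stop("flows not solved; run iterate_flow() first")
  n_c <- pmax(1L, as.integer(round(term$flow / q_c)))
  l_c <- with_private_seed(seed, rlnorm_trunc(nrow(term), dims$cap_length_mean,
                                              dims$cap_length_cv))
  chains <- data.frame(
    terminal_id = term$id,
    n_C = n_c,
    L_C = l_c,
    r_C = dims$capillary_diameter / 2,
    n_SV = pmax(1L, as.integer(round(n_c * dims$sv_ratio))),
    L_SV = dims$sv_length, r_SV = dims$sv_radius,
    n_LV = pmax(1L, as.integer(round(n_c * dims$lv_ratio))),
    L_LV = dims$lv_length, r_LV = dims$lv_radius,
    q = term$flow,
    p_in = net$nodes$pressure[match(term$to, net$nodes$id)])
  as_compartment_chains(chains)
}

#' Summarize the capillary-count distribution across chains
#'
#' @param chains a `compartment_chains` data.frame.
#' @param breaks histogram bin edges for capillaries-per-compartment
#'   (default 0 to the data maximum in steps of 250).
#' @return List with `total`, `median`, `mean`, and `histogram` (counts per
#'   bin with the bin edges).
#' @export
summarize_capillary_distribution <- function(chains, breaks = NULL) {
  stopifnot(nrow(chains) >= 1)
  n <- chains$n_C
  if (is.null(breaks)) breaks <- seq(0, 250 * ceiling(max(n) / 250), by = 250)
  h <- graphics::hist(n, breaks = breaks, plot = FALSE)
  list(total = sum(n), median = stats::median(n), mean = mean(n),
       histogram = list(breaks = h$breaks, counts = h$counts))
}

#' Preset study configurations for the two example branches
#'
#' Two frozen generator configurations emulating the statistical structure
#' of a pair of heterogeneous arteriolar branches fed by the same order-1
#' artery class: identical order diameters and boundary pressures, but
#' different branch counts, segment lengths and allocation asymmetry. The
#' first branch has more terminals with a lower median capillary count per
#' compartment; the second has fewer, longer pathways with longer
#' capillaries downstream. Per-order length statistics are calibration
#' choices of this package (chosen so downstream capillary totals land in
#' the tens of thousands with right-skewed per-compartment distributions),
#' not literature-reported values.
#'
#' @param seed generator seed.
#' @param n_terminals number of terminal arterioles; the defaults (220 and
#'   130) are the full-scale study conditions, smaller values give
#'   reduced-scale networks with the same statistical structure.
#' @return A [generator_config()].
#' @export
branch1_config <- function(seed = 101L, n_terminals = 220L) {
  generator_config(seed = seed, n_terminals = n_terminals,
                   order_length_mean = c(550, 480, 420, 400, 650) * 1.7,
                   asymmetry = 0.25, order_skip_prob = 0.1)
}

#' @rdname branch1_config
#' @export
branch2_config <- function(seed = 202L, n_terminals = 130L) {
  generator_config(seed = seed, n_terminals = n_terminals,
                   order_length_mean = c(550, 480, 420, 400, 650) * 1.4,
                   asymmetry = 0.25, order_skip_prob = 0.15)
}

#' @rdname branch1_config
#' @export
branch1_dims <- function() compartment_dims(cap_length_mean = 380)

#' @rdname branch1_config
#' @export
branch2_dims <- function() compartment_dims(cap_length_mean = 460)
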