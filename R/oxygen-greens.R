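# Green's-function solution of the tissue oxygen field around the
# arteriolar network. Vessels are discrete line sources whose strengths are
# chosen so the field at each vessel surface matches the local blood PO2;
# tissue points are Michaelis-Menten oxygen sinks on a regular grid. The
# field is represented as a uniform background level plus free-space kernel
# contributions of all sources and sinks, with the background level
# determined by the global source-sink balance (zero net flux leaves the
# domain, as for an insulated tissue region). Sink-sink interactions on the
# regular grid are evaluated exactly by FFT convolution.

#' Tissue domain around a vascular network
#'
#' A regular grid of tissue points with spacing `spacing` covering the
#' network bounding box (plus padding), clipped to points within
#' `sleeve` um of the nearest vessel axis: the arteriolar tissue region.
#' If `total_volume` is given, the points closest to the vessels are kept
#' until their summed volume reaches it; otherwise the sleeve alone defines
#' the region and its volume is `n_points * spacing^3`.
#'
#' @param net a `vascular_network`.
#' @param spacing grid spacing, um.
#' @param sleeve maximum distance from a vessel axis, um.
#' @param pad padding added around the network bounding box, um.
#' @param total_volume optional tissue volume, cm^3.
#' @param bbox optional 2x3 matrix (rows: lower and upper corner, um)
#'   overriding the network-derived bounding box (no padding applied).
#' @return A `tissue_domain`: data frame `points` (x, y, z um; volume cm^3),
#'   grid metadata (`origin`, `spacing`, `dims`, `grid_index`), and
#'   `total_volume`.
#' @export
tissue_domain <- function(net, spacing = 25, sleeve = 100, pad = 50,
                          total_volume = NULL, bbox = NULL) {
  nd <- net$nodes
  if (is.null(bbox)) {
    lo <- c(min(nd$x), min(nd$y), min(nd$z)) - pad
    hi <- c(max(nd$x), max(nd$y), max(nd$z)) + pad
  } else {
    lo <- bbox[1, ]; hi <- bbox[2, ]
  }
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  gx <- lo[1] + spacing * (seq_len(dims[1]) - 1L)
  gy <- lo[2] + spacing * (seq_len(dims[2]) - 1L)
  gz <- lo[3] + spacing * (seq_len(dims[3]) - 1L)
  pts <- expand.grid(x = gx, y = gy, z = gz, KEEP.OUT.ATTRS = FALSE)
  dd <- distance_to_segments(as.matrix(pts), net, with_radius = TRUE)
  # exclude intravascular (lumen) points: tissue starts at the vessel wall
  outside <- dd$dist > dd$radius + spacing / 4
  keep <- which(outside & dd$dist <= sleeve)
  if (!is.null(total_volume)) {
    n_keep <- max(8L, min(sum(outside),
                          round(total_volume / (um_to_cm(spacing))^3)))
    keep <- which(outside)[order(dd$dist[outside])[seq_len(n_keep)]]
    keep <- sort(keep)
  }
  if (length(keep) < 8) stop("tissue domain is empty; increase sleeve/pad")
  vol_pt <- um_to_cm(spacing)^3
  points <- pts[keep, , drop = FALSE]
  points$volume <- vol_pt
  rownames(points) <- NULL
  structure(list(points = points, origin = lo, spacing = spacing,
                 dims = dims, grid_index = keep,
                 total_volume = vol_pt * length(keep),
                 cache = new.env(parent = emptyenv())),
            class = "tissue_domain")
}

# minimum distance (um) from each point (n x 3 matrix) to any segment axis;
# with_radius = TRUE also returns the radius of the nearest segment
distance_to_segments <- function(p, net, with_radius = FALSE) {
  nd <- net$nodes; sg <- net$segments
  a <- as.matrix(nd[match(sg$from, nd$id), c("x", "y", "z")])
  b <- as.matrix(nd[match(sg$to, nd$id), c("x", "y", "z")])
  dmin <- rep(Inf, nrow(p))
  rad <- rep(0, nrow(p))
  for (k in seq_len(nrow(sg))) {
    ab <- b[k, ] - a[k, ]
    len2 <- sum(ab^2)
    t <- ((p[, 1] - a[k, 1]) * ab[1] + (p[, 2] - a[k, 2]) * ab[2] +
            (p[, 3] - a[k, 3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- p[, 1] - (a[k, 1] + t * ab[1])
    dy <- p[, 2] - (a[k, 2] + t * ab[2])
    dz <- p[, 3] - (a[k, 3] + t * ab[3])
    dk <- sqrt(dx * dx + dy * dy + dz * dz)
    closer <- dk < dmin
    dmin[closer] <- dk[closer]
    rad[closer] <- sg$diameter[k] / 2
  }
  if (with_radius) list(dist = dmin, radius = rad) else dmin
}

# Split segments into source elements of length <= max_factor * diameter
# (but never shorter than the vessel radius, below which the surface-match
# rows become nearly collinear). Returns a data.frame: segment index,
# element midpoint (um), length (um), radius (um), axial position (um).
discretize_segments <- function(net, max_factor = 2) {
  nd <- net$nodes; sg <- net$segments
  out <- vector("list", nrow(sg))
  for (k in seq_len(nrow(sg))) {
    a <- unlist(nd[match(sg$from[k], nd$id), c("x", "y", "z")])
    b <- unlist(nd[match(sg$to[k], nd$id), c("x", "y", "z")])
    el_len <- max(max_factor * sg$diameter[k], sg$diameter[k] / 2)
    n_el <- max(1L, ceiling(sg$length[k] / el_len))
    s_end <- sg$length[k] * seq_len(n_el) / n_el
    s_mid <- s_end - sg$length[k] / (2 * n_el)
    frac <- s_mid / sg$length[k]
    out[[k]] <- data.frame(
      seg = k,
      x = a[1] + frac * (b[1] - a[1]),
      y = a[2] + frac * (b[2] - a[2]),
      z = a[3] + frac * (b[3] - a[3]),
      len = sg$length[k] / n_el,
      radius = sg$diameter[k] / 2,
      s_mid = s_mid)
  }
  el <- do.call(rbind, out)
  rownames(el) <- NULL
  el
}

# free-space kernel value (mmHg per cm^3 O2/s) with a near-field floor at
# the source radius
greens_kernel <- function(dist_cm, krogh_coeff, floor_cm = 0) {
  1 / (4 * pi * krogh_coeff * pmax(dist_cm, floor_cm))
}

# FFT-based discrete convolution of grid sink strengths with the kernel.
# Returns a function(m_grid_values_at_kept_points) -> field at kept points.
make_sink_convolver <- function(domain, krogh_coeff, mirror = FALSE) {
  dims <- domain$dims
  h_cm <- um_to_cm(domain$spacing)
  # pad to highly composite sizes for the FFT; the mirror mode needs room
  # for both face reflections per axis without circular collision
  base <- if (mirror) 3L * dims else 2L * dims
  pd <- vapply(base, function(n) stats::nextn(n, c(2, 3, 5)), integer(1))
  if (mirror) {
    # minimum-image distances: reflected sink copies fill the padded box,
    # so every circular offset carries a genuine interaction
    off_mi <- function(n, p) {
      v <- 0:(p - 1L)
      pmin(v, p - v)
    }
    ox <- off_mi(dims[1], pd[1]); oy <- off_mi(dims[2], pd[2])
    oz <- off_mi(dims[3], pd[3])
  } else {
    off <- function(n, p) {
      v <- integer(p)
      v[1:n] <- 0:(n - 1L)
      v[(p - n + 2L):p] <- -((n - 1L):1L)
      v
    }
    ox <- off(dims[1], pd[1]); oy <- off(dims[2], pd[2]); oz <- off(dims[3], pd[3])
  }
  r2 <- outer(outer(ox^2, oy^2, `+`), oz^2, `+`)
  r_cm <- h_cm * sqrt(r2)
  kern <- 1 / (4 * pi * krogh_coeff * r_cm)
  kern[!is.finite(kern)] <- 0  # origin and (free mode) unused padding slots
  # self term: sink spread uniformly over its cell (equal-volume sphere)
  r_eq <- h_cm * (3 / (4 * pi))^(1 / 3)
  kern[1, 1, 1] <- 3 / (2 * r_eq) / (4 * pi * krogh_coeff)
  kern_fft <- stats::fft(kern)
  idx <- domain$grid_index

  # index maps for even ("whole-sample") reflection about the two face
  # planes of each axis, wrapped into the padded circular box
  reflections <- function(n, p) {
    list(orig = list(src = 1:n, dst = 1:n),
         low  = list(src = 2:n, dst = p - (2:n) + 2L),
         high = list(src = 1:(n - 1L), dst = 2L * n - (1:(n - 1L))))
  }
  rx <- reflections(dims[1], pd[1]); ry <- reflections(dims[2], pd[2])
  rz <- reflections(dims[3], pd[3])

  # returns the full grid field of the sinks (3-D array over the domain
  # grid); the caller reads tissue points and interpolates vessel elements
  # from the same discrete field
  function(m_kept) {
    mfull <- numeric(prod(dims))
    mfull[idx] <- m_kept
    marr <- array(mfull, dim = dims)
    mg <- array(0, dim = pd)
    if (mirror) {
      for (cx in rx) for (cy in ry) for (cz in rz) {
        mg[cx$dst, cy$dst, cz$dst] <- mg[cx$dst, cy$dst, cz$dst] +
          marr[cx$src, cy$src, cz$src]
      }
    } else {
      mg[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- marr
    }
    conv <- stats::fft(stats::fft(mg) * kern_fft, inverse = TRUE) / prod(pd)
    Re(conv[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])])
  }
}

# trilinear interpolation weights of arbitrary points on the domain grid:
# returns an n_pts x 8 index matrix and weight matrix
trilinear_weights <- function(domain, xyz) {
  dims <- domain$dims
  f <- sweep(sweep(xyz, 2, domain$origin), 2, rep(domain$spacing, 3), "/")
  i0 <- pmin(pmax(floor(f), 0), dims - 2L)
  t <- f - i0
  idx <- matrix(0L, nrow(xyz), 8)
  w <- matrix(0, nrow(xyz), 8)
  k <- 1L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    idx[, k] <- (i0[, 3] + dz) * dims[1] * dims[2] +
      (i0[, 2] + dy) * dims[1] + (i0[, 1] + dx) + 1L
    w[, k] <- (dx * t[, 1] + (1 - dx) * (1 - t[, 1])) *
      (dy * t[, 2] + (1 - dy) * (1 - t[, 2])) *
      (dz * t[, 3] + (1 - dz) * (1 - t[, 3]))
    k <- k + 1L
  }
  list(idx = idx, w = w)
}

# Vectorized inversion of the blood oxygen content per unit volume,
# c(P) = H_D C0 S(P) + alpha_b P (cm^3 O2 / cm^3 blood): Newton iteration
# with uniroot fallback. c is strictly increasing in P.
invert_blood_content <- function(c_target, params, p_start = NULL) {
  n_h <- params$hill_n; p50n <- params$p50^n_h
  hc <- params$hd * params$c0; ab <- params$alpha_b
  cfun <- function(p) hc * p^n_h / (p^n_h + p50n) + ab * p
  out <- numeric(length(c_target))
  pos <- c_target > 0
  if (!any(pos)) return(out)
  p <- if (is.null(p_start)) rep(30, sum(pos)) else pmax(p_start[pos], 1e-3)
  ct <- c_target[pos]
  for (it in 1:60) {
    pn <- p^n_h
    s <- pn / (pn + p50n)
    ds <- n_h * pn * p50n / (p * (pn + p50n)^2)
    step <- (hc * s + ab * p - ct) / (hc * ds + ab)
    p_new <- pmax(p - step, p / 4)
    if (max(abs(p_new - p)) < 1e-12) { p <- p_new; break }
    p <- p_new
  }
  bad <- abs(cfun(p) - ct) > 1e-12 * pmax(ct, 1e-6)
  for (i in which(bad)) {
    upper <- 200
    while (cfun(upper) < ct[i]) upper <- upper * 2
    p[i] <- stats::uniroot(function(x) cfun(x) - ct[i], c(0, upper),
                           tol = 1e-13)$root
  }
  out[pos] <- p
  out
}

# March blood PO2 down the tree given per-element source strengths qs
# (cm^3 O2/s, >= 0 enforced). The oxygen content per unit blood volume is
# conserved at diverging nodes (children inherit the parent outlet
# content), so only element midpoints and outlets need inversion.
march_blood_po2 <- function(net, el, qs, params, p_start = NULL) {
  sg <- net$segments
  qs <- pmax(qs, 0)
  p_inlet <- inverse_hill(params$inlet_saturation, params)
  c_inlet <- params$hd * params$c0 * params$inlet_saturation +
    params$alpha_b * p_inlet
  node_c <- stats::setNames(rep(NA_real_, nrow(net$nodes)), net$nodes$id)
  node_c[as.character(net$inlet_node)] <- c_inlet
  el_by_seg <- split(seq_len(nrow(el)), el$seg)
  n_el <- nrow(el)
  c_mid <- numeric(n_el)
  q_el <- numeric(n_el)
  seg_cout <- numeric(nrow(sg))
  for (k in segment_topo_order(net)) {
    q <- nlmin_to_cgs(abs(sg$flow[k]))
    idx <- el_by_seg[[as.character(k)]]
    f_in <- node_c[as.character(sg$from[k])] * q
    f_ends <- f_in - cumsum(qs[idx])
    c_mid[idx] <- pmax((f_ends + qs[idx] / 2) / q, 0)
    q_el[idx] <- q
    c_out <- max(f_ends[length(f_ends)] / q, 0)
    node_c[as.character(sg$to[k])] <- c_out
    seg_cout[k] <- c_out
  }
  el_p <- invert_blood_content(c_mid, params, p_start)
  seg_out <- invert_blood_content(seg_cout, params)
  sat_el <- hill_saturation(el_p, params)
  seg_sat <- vapply(seq_len(nrow(sg)), function(k)
    mean(sat_el[el_by_seg[[as.character(k)]]]), numeric(1))
  list(el_p = el_p, seg_sat = seg_sat, seg_out = seg_out,
       node_c = node_c)
}

#' Solve the tissue oxygen field by the Green's-function method
#'
#' Self-consistent solution of steady oxygen transport around the
#' arteriolar network: vessel source strengths are solved so the
#' superposed field matches the blood PO2 at every vessel element surface
#' (intravascular wall resistance neglected), blood PO2 is convected along
#' the tree losing the solved efflux, tissue consumption follows
#' Michaelis-Menten kinetics `M0 P/(P0 + P)` at every tissue point, and a
#' uniform background level enforces the global balance between vessel
#' efflux and tissue consumption. The nonlinear system is solved by Picard
#' iteration with under-relaxation.
#'
#' @param net a converged `vascular_network` (flows solved).
#' @param domain a [tissue_domain()].
#' @param params an [oxygen_params()].
#' @param max_iter,tol Picard iteration controls (`tol` in mmHg, maximum
#'   tissue PO2 change per iteration).
#' @param relax under-relaxation factor in (0, 1].
#' @param fixed_blood_po2 optional: hold the blood PO2 at this constant
#'   value everywhere instead of convecting it (used for validation against
#'   the finite-difference oracle).
#' @param warm optional `oxygen_field` from a previous solve on the same
#'   domain (e.g. the previous regulation step) used as the initial
#'   iterate; greatly reduces the iteration count when the network has
#'   changed only slightly.
#' @param max_factor source elements are at most `max_factor` vessel
#'   diameters long (smaller values refine the surface matching).
#' @param boundary `"free"` treats the domain as effectively unbounded
#'   (free-space kernel; the canonical baseline for an open tissue region
#'   around a network). `"mirror"` adds the first shell of mirror images of
#'   all sources and sinks across the bounding-box faces, approximating a
#'   closed (zero-flux) box; use it when the domain is a physical box, as
#'   in comparisons against [finite_difference_oracle()].
#' @return An `oxygen_field`: `tissue` (points with `po2`, mmHg, clamped at
#'   0, and `volume`), `elements` (per source element: position, blood PO2
#'   `p_b`, saturation, source strength `qs` in cm^3 O2/s), `segment_sat`
#'   and `terminal_po2` summaries, `p_inf` (background level), and
#'   `balance` (total efflux, total consumption, relative residual).
#' @export
solve_greens_field <- function(net, domain, params = oxygen_params(),
                               max_iter = 200L, tol = 0.01, relax = 0.5,
                               fixed_blood_po2 = NULL, warm = NULL,
                               max_factor = 2, boundary = c("free", "mirror")) {
  boundary <- match.arg(boundary)
  sg <- net$segments
  if (is.null(fixed_blood_po2) && anyNA(sg$flow))
    stop("flows not solved; run iterate_flow() first")
  k_o2 <- params$krogh_coeff
  el <- discretize_segments(net, max_factor)
  n_el <- nrow(el)
  pts <- domain$points
  n_t <- nrow(pts)

  # vessel-vessel kernel in the surface convention: every element is a
  # finite line source whose averaged potential at distance rho is
  # 2 asinh(l/(2 rho)) / (4 pi K l) (the point kernel 1/(4 pi K rho) in the
  # far field, the line self-potential at rho = a); evaluation at a matched
  # element's wall uses the effective distance sqrt(d_axis^2 + a_i^2).
  # Using one convention for wall matching and tissue evaluation keeps the
  # two fields consistent in the near zone.
  exy <- as.matrix(el[, c("x", "y", "z")])
  dvv <- as.matrix(stats::dist(exy))
  a_cm <- um_to_cm(el$radius)
  l_cm <- um_to_cm(el$len)
  line_kernel <- function(rho_cm, l_source_cm) {
    2 * asinh(l_source_cm / (2 * rho_cm)) / (4 * pi * k_o2 * l_source_cm)
  }
  d_eff <- sqrt(um_to_cm(dvv)^2 + a_cm^2)  # a_cm recycles by row
  gvv <- line_kernel(d_eff, rep(l_cm, each = n_el))

  # first-shell mirror images of the source elements across the box faces
  img_coords <- NULL
  if (boundary == "mirror") {
    lo <- domain$origin
    hi <- domain$origin + (domain$dims - 1L) * domain$spacing
    refl <- function(c0, axis) {
      list(c0[, axis], 2 * lo[axis] - c0[, axis], 2 * hi[axis] - c0[, axis])
    }
    img_coords <- list()
    cx <- refl(exy, 1); cy <- refl(exy, 2); cz <- refl(exy, 3)
    for (i1 in 1:3) for (i2 in 1:3) for (i3 in 1:3) {
      if (i1 == 1 && i2 == 1 && i3 == 1) next
      img_coords[[length(img_coords) + 1L]] <- cbind(cx[[i1]], cy[[i2]], cz[[i3]])
    }
    for (im in img_coords) {
      for (j in seq_len(n_el)) {
        dd <- sqrt((exy[, 1] - im[j, 1])^2 + (exy[, 2] - im[j, 2])^2 +
                     (exy[, 3] - im[j, 3])^2)
        gvv[, j] <- gvv[, j] +
          line_kernel(sqrt(um_to_cm(dd)^2 + a_cm^2), l_cm[j])
      }
    }
  }
  # bordered system: segment-averaged wall-PO2 match rows + the global
  # balance row. Source strength is one unknown per SEGMENT (per unit
  # length, uniform along the segment): per-element unknowns collocated
  # only at element midpoints are nearly collinear for parallel vessels a
  # few radii apart, and the resulting ill-conditioned solve concentrates
  # flux into single elements with large spurious field bulges between
  # collocation points. Strengths are constrained non-negative (oxygen
  # only leaves the blood): a segment whose unconstrained strength turns
  # negative (counter-current contact) is clamped to zero and its wall
  # equation released, by a small active-set iteration with cached
  # factorizations.
  seg_of <- el$seg
  n_seg <- nrow(sg)
  w_avg <- matrix(0, n_seg, n_el)
  m_len <- matrix(0, n_el, n_seg)
  for (s in seq_len(n_seg)) {
    e_s <- which(seg_of == s)
    w_avg[s, e_s] <- 1 / length(e_s)
    m_len[e_s, s] <- l_cm[e_s]
  }
  l_seg <- colSums(m_len)
  a_ss <- w_avg %*% gvv %*% m_len
  g0 <- stats::median(diag(a_ss))
  a_sc <- a_ss / g0
  inv_cache <- new.env()
  solve_sources <- function(rhs_wall, m_tot_scaled) {
    rhs_avg <- as.numeric(w_avg %*% rhs_wall)
    active <- rep(TRUE, n_seg)
    u_s <- numeric(n_seg); p_inf_s <- 0
    for (pass in 1:10) {
      key <- paste0("k", paste(which(!active), collapse = ","))
      a_inv <- inv_cache[[key]]
      if (is.null(a_inv)) {
        na <- sum(active)
        a_sys <- rbind(cbind(a_sc[active, active, drop = FALSE], 1),
                       c(l_seg[active] / mean(l_seg), 0))
        a_inv <- solve(a_sys)
        inv_cache[[key]] <- a_inv
      }
      na <- sum(active)
      sol <- a_inv %*% c(rhs_avg[active], m_tot_scaled / mean(l_seg))
      u_s <- numeric(n_seg)
      u_s[active] <- sol[seq_len(na)]
      p_inf_s <- sol[na + 1L]
      neg <- active & u_s < -1e-9 * max(abs(u_s))
      # released segments whose surface field falls below the blood PO2
      # must rejoin the active set
      surf <- as.numeric(a_sc %*% u_s) + p_inf_s
      rejoin <- !active & (surf < rhs_avg - 1e-9 * max(abs(rhs_avg)))
      if (!any(neg) && !any(rejoin)) break
      active <- (active & !neg) | rejoin
      if (!any(active)) break
    }
    list(qs_scaled = as.numeric(m_len %*% pmax(u_s, 0)),
         p_inf_scaled = p_inf_s)
  }

  # tissue-vessel kernel in the same line-source convention
  gtv <- matrix(0, n_t, n_el)
  for (j in seq_len(n_el)) {
    dd <- sqrt((pts$x - el$x[j])^2 + (pts$y - el$y[j])^2 + (pts$z - el$z[j])^2)
    gtv[, j] <- line_kernel(pmax(um_to_cm(dd), a_cm[j]), l_cm[j])
  }
  if (!is.null(img_coords)) {
    for (im in img_coords) {
      for (j in seq_len(n_el)) {
        dd <- sqrt((pts$x - im[j, 1])^2 + (pts$y - im[j, 2])^2 +
                     (pts$z - im[j, 3])^2)
        gtv[, j] <- gtv[, j] +
          line_kernel(pmax(um_to_cm(dd), a_cm[j]), l_cm[j])
      }
    }
  }
  conv_key <- paste0("conv_", format(k_o2), "_", boundary)
  sink_conv <- domain$cache[[conv_key]]
  if (is.null(sink_conv)) {
    sink_conv <- make_sink_convolver(domain, k_o2,
                                     mirror = boundary == "mirror")
    domain$cache[[conv_key]] <- sink_conv
  }
  kept_idx <- domain$grid_index
  el_interp <- trilinear_weights(domain, exy)

  m0_cgs <- m0_to_cgs(params$m0)
  vol <- pts$volume
  # the continuous diffusion-consumption field obeys a maximum principle:
  # tissue PO2 cannot exceed the highest blood PO2; the discrete
  # superposition can bulge above it between collocation points near
  # closely spaced vessels, so the bound is enforced on the iterate
  p_max <- if (is.null(fixed_blood_po2))
    inverse_hill(params$inlet_saturation, params) else max(fixed_blood_po2)
  p_t <- rep(inverse_hill(params$inlet_saturation, params) / 2, n_t)
  p_b_el <- rep(if (is.null(fixed_blood_po2))
    inverse_hill(params$inlet_saturation, params) else fixed_blood_po2, n_el)
  qs <- rep(0, n_el)
  if (!is.null(warm) && nrow(warm$tissue) == n_t &&
      nrow(warm$elements) == n_el) {
    p_t <- warm$p_t_raw
    qs <- warm$elements$qs
    if (is.null(fixed_blood_po2)) p_b_el <- warm$elements$p_b
  }
  converged <- FALSE
  # fixed-point iteration on the tissue field with adaptive (Irons-Tuck /
  # Aitken) mixing: the Michaelis-Menten sink feedback can carry a loop
  # gain above one at high demand, which a fixed under-relaxation factor
  # cannot stabilise
  omega <- relax
  r_prev <- NULL
  for (iter in seq_len(max_iter)) {
    m <- vol * m0_cgs * pmax(p_t, 0) / (params$p0 + pmax(p_t, 0))
    sink_field <- sink_conv(m)
    s_v <- as.numeric(rowSums(matrix(sink_field[el_interp$idx], n_el, 8) *
                                el_interp$w))
    sol <- solve_sources(p_b_el + s_v, sum(m) * g0)
    qs <- sol$qs_scaled / g0
    p_inf <- sol$p_inf_scaled
    if (is.null(fixed_blood_po2)) {
      blood <- march_blood_po2(net, el, qs, params, p_start = p_b_el)
      p_b_el <- blood$el_p
    }
    p_t_new <- pmin(p_inf + as.numeric(gtv %*% qs) - sink_field[kept_idx],
                    p_max)
    r <- p_t_new - p_t
    dp <- max(abs(r))
    if (dp < tol) { converged <- TRUE; break }
    if (!is.null(r_prev)) {
      dr <- r - r_prev
      denom <- sum(dr * dr)
      if (denom > 0) omega <- -omega * sum(r_prev * dr) / denom
      omega <- min(max(omega, 0.05), 1)
    }
    p_t <- pmin(p_t + omega * r, p_max)
    r_prev <- r
  }
  if (!converged)
    warning(sprintf("Green's iteration stopped at %d iterations (dPO2 %.3g mmHg)",
                    max_iter, dp))
  if (is.null(fixed_blood_po2)) {
    blood <- march_blood_po2(net, el, qs, params, p_start = p_b_el)
  } else {
    blood <- list(el_p = p_b_el, seg_sat = rep(NA_real_, nrow(sg)),
                  seg_out = rep(NA_real_, nrow(sg)), node_p = NULL)
  }
  m <- vol * m0_cgs * pmax(p_t, 0) / (params$p0 + pmax(p_t, 0))
  efflux <- sum(pmax(qs, 0))
  consumption <- sum(m)
  tissue <- pts
  tissue$po2 <- pmax(p_t, 0)
  el$p_b <- blood$el_p
  el$saturation <- hill_saturation(pmax(blood$el_p, 0), params)
  el$qs <- qs
  term_idx <- which(sg$terminal)
  structure(list(
    tissue = tissue, elements = el, p_t_raw = p_t,
    segment_sat = blood$seg_sat,
    terminal_po2 = stats::setNames(blood$seg_out[term_idx], sg$id[term_idx]),
    p_inf = p_inf,
    clamped_fraction = sum(vol[p_t < 0]) / sum(vol),
    balance = list(efflux = efflux, consumption = consumption,
                   residual = abs(efflux - consumption) /
                     max(consumption, 1e-300)),
    iterations = iter, converged = converged, params = params),
    class = "oxygen_field")
}

#' @export
print.oxygen_field <- function(x, ...) {
  cat("<oxygen_field> ", nrow(x$tissue), " tissue points, ",
      nrow(x$elements), " vessel source elements\n", sep = "")
  cat(sprintf("  tissue PO2: median %.1f mmHg, range [%.1f, %.1f]\n",
              stats::median(x$tissue$po2), min(x$tissue$po2), max(x$tissue$po2)))
  cat(sprintf("  O2 balance: efflux %.3g, consumption %.3g cm^3 O2/s (residual %.2g%%)\n",
              x$balance$efflux, x$balance$consumption, 100 * x$balance$residual))
  invisible(x)
}

#' Fraction of tissue below PO2 thresholds
#'
#' Volume-weighted fraction of tissue points with PO2 below each threshold;
#' the hypoxic-burden curve used to compare networks.
#'
#' @param field an `oxygen_field` (or any data frame with `po2` and
#'   `volume` columns).
#' @param thresholds PO2 thresholds, mmHg (default 0 to 60 in steps of 1).
#' @return data.frame with `threshold` and `fraction` (non-decreasing).
#' @export
fraction_below_threshold <- function(field, thresholds = 0:60) {
  tissue <- if (inherits(field, "oxygen_field")) field$tissue else field
  w <- tissue$volume / sum(tissue$volume)
  frac <- vapply(thresholds, function(t) sum(w[tissue$po2 < t]), numeric(1))
  data.frame(threshold = thresholds, fraction = frac)
}

#' Finite-difference oracle for the tissue oxygen field
#'
#' Independent validator for [solve_greens_field()]: solves the steady
#' diffusion-consumption equation on a regular grid over a box by a
#' 7-point Laplacian with zero-flux (reflection) box boundaries, Dirichlet
#' conditions on cells within a vessel radius of a segment axis (held at
#' the vessel blood PO2), and Michaelis-Menten consumption handled by
#' Picard iteration with a sparse Cholesky factorization. Optionally the
#' box faces can be held at a fixed PO2 (`outer_dirichlet`) for analytic
#' line-source checks.
#'
#' @param net a `vascular_network` (small: a few segments).
#' @param bbox 2x3 matrix: lower and upper corners of the box, um.
#' @param n grid points per axis (scalar or length-3).
#' @param params an [oxygen_params()].
#' @param blood_po2 vessel-wall PO2: scalar, or vector per segment.
#' @param outer_dirichlet optional fixed PO2 on the box faces, mmHg.
#' @param dirichlet_axes which axes' faces take the fixed value (default
#'   all three); remaining faces stay zero-flux, e.g. for quasi-2-D slab
#'   checks with a vessel along the third axis.
#' @param max_iter,tol Picard controls (tol in mmHg).
#' @return List: `grid` data frame (x, y, z, po2), `dims`, `spacing` (um),
#'   `vessel_mask` (logical), `iterations`.
#' @export
finite_difference_oracle <- function(net, bbox, n = 41L,
                                     params = oxygen_params(),
                                     blood_po2 = 50,
                                     outer_dirichlet = NULL,
                                     dirichlet_axes = 1:3,
                                     max_iter = 100L, tol = 0.005) {
  n <- rep_len(as.integer(n), 3L)
  lo <- bbox[1, ]; hi <- bbox[2, ]
  h <- (hi - lo) / (n - 1L)
  if (max(abs(h - h[1])) > 1e-9 * h[1])
    stop("finite_difference_oracle requires cubic cells; adjust bbox or n")
  h <- h[1]
  gx <- seq(lo[1], hi[1], length.out = n[1])
  gy <- seq(lo[2], hi[2], length.out = n[2])
  gz <- seq(lo[3], hi[3], length.out = n[3])
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz, KEEP.OUT.ATTRS = FALSE))
  np <- nrow(pts)
  sg <- net$segments
  if (min(sg$diameter) / 2 < h / 2)
    warning("grid spacing exceeds a vessel radius; vessel poorly resolved")
  blood_po2 <- rep_len(blood_po2, nrow(sg))

  # vessel mask: cells within the segment radius of a segment axis
  vessel <- rep(FALSE, np)
  vessel_p <- rep(0, np)
  nd <- net$nodes
  for (k in seq_len(nrow(sg))) {
    a <- unlist(nd[match(sg$from[k], nd$id), c("x", "y", "z")])
    b <- unlist(nd[match(sg$to[k], nd$id), c("x", "y", "z")])
    ab <- b - a; len2 <- sum(ab^2)
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
            (pts[, 3] - a[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    dd <- sqrt((pts[, 1] - (a[1] + t * ab[1]))^2 +
                 (pts[, 2] - (a[2] + t * ab[2]))^2 +
                 (pts[, 3] - (a[3] + t * ab[3]))^2)
    hit <- dd <= sg$diameter[k] / 2
    vessel[hit] <- TRUE
    vessel_p[hit] <- blood_po2[k]
  }
  outer <- rep(FALSE, np)
  if (!is.null(outer_dirichlet)) {
    ii <- arrayInd(seq_len(np), n)
    for (ax in dirichlet_axes) {
      outer <- outer | ii[, ax] %in% c(1L, n[ax])
    }
    outer <- outer & !vessel
  }
  fixed <- vessel | outer
  fixed_val <- ifelse(vessel, vessel_p,
                      if (is.null(outer_dirichlet)) 0 else outer_dirichlet)

  # 7-point Laplacian over free cells. Box faces are zero-flux (mirror
  # reflection). At the vessel wall the stencil uses Shortley-Weller
  # irregular arms: the arm length to the actual cylinder surface (fraction
  # theta of h) replaces the full grid arm, removing the first-order
  # staircase bias of a plain Dirichlet-cell representation.
  idx3 <- function(i, j, k) (k - 1L) * n[1] * n[2] + (j - 1L) * n[1] + i
  ii <- arrayInd(seq_len(np), n)
  free <- which(!fixed)
  nf <- length(free)
  remap <- integer(np); remap[free] <- seq_along(free)

  # fraction of h from point p along +/- axis direction to the nearest
  # cylinder surface (infinite-cylinder geometry; vessels are assumed to
  # span the box or end outside it)
  wall_theta <- function(p_idx, axis, sgn) {
    p <- pts[p_idx, , drop = FALSE]
    th <- rep(1, length(p_idx))
    for (k in seq_len(nrow(sg))) {
      a <- unlist(nd[match(sg$from[k], nd$id), c("x", "y", "z")])
      b <- unlist(nd[match(sg$to[k], nd$id), c("x", "y", "z")])
      nhat <- (b - a) / sqrt(sum((b - a)^2))
      e <- c(0, 0, 0); e[axis] <- sgn * h
      e_perp <- e - sum(e * nhat) * nhat
      u <- sweep(p, 2, a)
      u_par <- u %*% nhat
      u_perp <- u - u_par %*% t(nhat)
      aa <- sum(e_perp^2)
      bb <- 2 * as.numeric(u_perp %*% e_perp)
      cc <- rowSums(u_perp^2) - (sg$diameter[k] / 2)^2
      disc <- bb^2 - 4 * aa * cc
      ok <- disc >= 0 & aa > 0
      t1 <- rep(Inf, length(p_idx))
      t1[ok] <- (-bb[ok] - sqrt(disc[ok])) / (2 * aa)
      hit <- ok & t1 > 0 & t1 <= 1
      th[hit] <- pmin(th[hit], t1[hit])
    }
    th
  }

  # finite-volume fluxes: a regular face has conductance 1, a face cut by
  # the vessel wall has conductance 1/theta to the wall value (theta = the
  # arm fraction to the actual cylinder surface). Symmetric by
  # construction, so a single sparse Cholesky factorization serves every
  # Picard iteration. Box faces are zero-flux (missing faces carry none).
  trip_i <- trip_j <- integer(0); trip_x <- numeric(0)
  diag_v <- numeric(nf)
  rhs_fix <- numeric(nf)
  for (axis in 1:3) {
    for (sgn in c(-1L, 1L)) {
      nbr <- ii[free, , drop = FALSE]
      nbr[, axis] <- nbr[, axis] + sgn
      inside <- nbr[, axis] >= 1L & nbr[, axis] <= n[axis]
      tgt <- rep(NA_integer_, nf)
      tgt[inside] <- idx3(nbr[inside, 1], nbr[inside, 2], nbr[inside, 3])
      isfree <- inside & !fixed[tgt]
      iswall <- inside & fixed[tgt] & vessel[tgt]
      isouter <- inside & fixed[tgt] & !vessel[tgt]
      # free-free face
      trip_i <- c(trip_i, which(isfree))
      trip_j <- c(trip_j, remap[tgt[isfree]])
      trip_x <- c(trip_x, rep(-1, sum(isfree)))
      diag_v[isfree] <- diag_v[isfree] + 1
      # face cut by the vessel wall at fraction theta of the arm
      wl <- which(iswall)
      if (length(wl)) {
        th <- pmax(wall_theta(free[wl], axis, sgn), 0.05)
        diag_v[wl] <- diag_v[wl] + 1 / th
        rhs_fix[wl] <- rhs_fix[wl] + fixed_val[tgt[wl]] / th
      }
      # outer Dirichlet face (box faces held at a fixed PO2)
      diag_v[isouter] <- diag_v[isouter] + 1
      rhs_fix[isouter] <- rhs_fix[isouter] + fixed_val[tgt[isouter]]
    }
  }
  amat <- Matrix::sparseMatrix(i = c(trip_i, seq_len(nf)),
                               j = c(trip_j, seq_len(nf)),
                               x = c(trip_x, diag_v),
                               dims = c(nf, nf))
  ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(amat), "CsparseMatrix"),
                         LDL = FALSE)

  k_o2 <- params$krogh_coeff
  h_cm <- um_to_cm(h)
  m0_cgs <- m0_to_cgs(params$m0)
  p <- rep(mean(blood_po2) / 2, nf)
  for (iter in seq_len(max_iter)) {
    cons <- m0_cgs * pmax(p, 0) / (params$p0 + pmax(p, 0))  # per cm^3
    rhs <- rhs_fix - cons * h_cm^2 / k_o2
    p_new <- as.numeric(Matrix::solve(ch, rhs))
    dp <- max(abs(p_new - p))
    p <- 0.6 * p_new + 0.4 * p
    if (dp < tol) break
  }
  po2 <- fixed_val
  po2[free] <- p
  list(grid = data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                         po2 = pmax(po2, 0)),
       dims = n, spacing = h, vessel_mask = vessel, iterations = iter)
}
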