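#' Three-shell spherical head model
#'
#' Concentric-spheres volume conductor (brain, skull, scalp) with
#' electrodes on the outer surface. This is the classical analytic EEG
#' forward model; radii are in metres and conductivities in S/m, with the
#' conventional ~1:1/80:1 skull contrast by default.
#'
#' @param montage Electrode montage on the unit sphere
#'   ([spherical_montage()]); positions are scaled to the scalp radius.
#' @param radii Increasing radii (m) of brain, skull and scalp surfaces.
#' @param conductivities Conductivity (S/m) of each compartment, innermost
#'   first.
#' @return List of class `head_model`: `radii`, `conductivities`,
#'   `montage`, `electrodes` (n x 3 matrix, metres).
#' @export
head_model <- function(montage = spherical_montage(192),
                       radii = c(brain = 0.087, skull = 0.092, scalp = 0.100),
                       conductivities = c(brain = 0.33, skull = 0.0042,
                                          scalp = 0.33)) {
  if (length(radii) != length(conductivities)) {
    abort("One conductivity per compartment is required.")
  }
  if (is.unsorted(radii, strictly = TRUE)) {
    abort("`radii` must be strictly increasing, innermost first.")
  }
  if (any(conductivities <= 0)) abort("Conductivities must be positive.")
  pos <- montage_positions(montage)
  pos <- pos / sqrt(rowSums(pos^2))        # exact unit sphere
  structure(list(
    radii = radii, conductivities = conductivities, montage = montage,
    electrodes = pos * radii[length(radii)]
  ), class = "head_model")
}

#' Regular source grid inside the brain compartment
#'
#' Nodes of a cubic lattice retained when strictly inside
#' `inner_fraction` of the innermost sphere radius (a safety margin keeps
#' the forward series well convergent and sources out of the skull).
#'
#' @param head A [head_model()].
#' @param spacing_mm Lattice spacing in mm (default 12 mm, ~1200 nodes).
#' @param inner_fraction Usable fraction of the brain radius.
#' @return List of class `source_grid`: `nodes` (n x 3 matrix, metres),
#'   `spacing` (metres).
#' @export
source_grid <- function(head, spacing_mm = 12, inner_fraction = 0.95) {
  stopifnot(inherits(head, "head_model"))
  stop_if_not_scalar_number(spacing_mm, "spacing_mm", lower = 1e-6)
  stop_if_not_scalar_number(inner_fraction, "inner_fraction", 0.1, 0.999)
  h <- spacing_mm / 1000
  r_max <- inner_fraction * head$radii[1]
  ax <- seq(-ceiling(r_max / h) * h, ceiling(r_max / h) * h, by = h)
  nodes <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  keep <- sqrt(rowSums(nodes^2)) < r_max
  structure(list(nodes = nodes[keep, , drop = FALSE], spacing = h),
            class = "source_grid")
}

# radial profile coefficient c_L(R) of the n-th spherical-harmonic term.
# In every layer the n-th term of the potential is
# c_j(r) * Theta_n(angles); layer 1 (source layer) has
# c_1(r) = r^-(n+1) + alpha_1 r^n (the first part is the infinite-medium
# dipole term), outer layers c_j(r) = alpha_j r^n + beta_j r^-(n+1).
# Continuity of V and sigma dV/dr at each interface plus dV/dr = 0 at the
# scalp give a small linear system per n, solved directly.
shell_radial_coef <- function(n_terms, radii, cond) {
  L <- length(radii)
  R <- radii[L]
  vapply(seq_len(n_terms), function(n) {
    if (L == 1L) {
      return(R^-(n + 1) * (2 * n + 1) / n)
    }
    # unknowns: alpha_1, then (alpha_j, beta_j) for j = 2..L
    n_unk <- 2L * L - 1L
    A <- matrix(0, n_unk, n_unk)
    rhs <- numeric(n_unk)
    a_idx <- function(j) if (j == 1L) 1L else 2L * (j - 1L)
    b_idx <- function(j) 2L * (j - 1L) + 1L
    row <- 0L
    for (j in seq_len(L - 1L)) {
      r <- radii[j]
      # potential continuity
      row <- row + 1L
      A[row, a_idx(j)] <- r^n
      if (j > 1L) A[row, b_idx(j)] <- r^-(n + 1)
      A[row, a_idx(j + 1L)] <- -r^n
      A[row, b_idx(j + 1L)] <- -r^-(n + 1)
      if (j == 1L) rhs[row] <- -r^-(n + 1)
      # radial current continuity
      row <- row + 1L
      A[row, a_idx(j)] <- cond[j] * n * r^(n - 1)
      if (j > 1L) A[row, b_idx(j)] <- -cond[j] * (n + 1) * r^-(n + 2)
      A[row, a_idx(j + 1L)] <- -cond[j + 1L] * n * r^(n - 1)
      A[row, b_idx(j + 1L)] <- cond[j + 1L] * (n + 1) * r^-(n + 2)
      if (j == 1L) rhs[row] <- cond[1L] * (n + 1) * r^-(n + 2)
    }
    # insulating outer boundary
    row <- row + 1L
    A[row, a_idx(L)] <- n * R^(n - 1)
    A[row, b_idx(L)] <- -(n + 1) * R^-(n + 2)
    sol <- solve(A, rhs)
    sol[a_idx(L)] * R^n + sol[b_idx(L)] * R^-(n + 1)
  }, numeric(1))
}

# P_n(x) and the associated P_n^1(x) = sqrt(1-x^2) P_n'(x) for n = 1..nmax,
# evaluated at a vector x; returns two nmax x length(x) matrices
legendre_terms <- function(x, nmax) {
  P <- matrix(0, nmax + 1L, length(x))
  P[1L, ] <- 1
  P[2L, ] <- x
  if (nmax >= 2L) {
    for (n in 2:nmax) {
      P[n + 1L, ] <- ((2 * n - 1) * x * P[n, ] - (n - 1) * P[n - 1L, ]) / n
    }
  }
  s <- sqrt(pmax(0, 1 - x^2))
  dP <- matrix(0, nmax, length(x))
  for (n in seq_len(nmax)) {
    # (1 - x^2) P_n'(x) = n (P_{n-1} - x P_n)
    dP[n, ] <- ifelse(s > 0, n * (P[n, ] - x * P[n + 1L, ]) / s, 0)
  }
  list(P = P[-1L, , drop = FALSE], P1 = dP)
}

#' Analytic dipole lead field for the spherical head model
#'
#' Surface potential of a current dipole inside a multilayer concentric
#' spherical conductor, from the Legendre series expansion with radial
#' coefficients obtained by solving the interface conditions per harmonic
#' degree. Three columns per grid node (x, y, z unit dipole moments);
#' rows are average-referenced, matching the reference-free convention of
#' the rest of the pipeline.
#'
#' @param head A [head_model()].
#' @param grid A [source_grid()]; all nodes must lie strictly inside the
#'   innermost sphere.
#' @param n_terms Series truncation order (default 60).
#' @return List of class `lead_field`: `L` (electrodes x 3*nodes matrix,
#'   V per A·m; columns ordered node-major x,y,z), `grid`, `head`.
#' @export
generate_forward <- function(head, grid, n_terms = 60) {
  stopifnot(inherits(head, "head_model"), inherits(grid, "source_grid"))
  n_terms <- stop_if_not_count(n_terms, "n_terms", lower = 5L)
  nodes <- grid$nodes
  if (any(sqrt(rowSums(nodes^2)) >= head$radii[1])) {
    abort("All source nodes must lie strictly inside the innermost sphere.")
  }
  elec <- head$electrodes
  R <- head$radii[length(head$radii)]
  e_hat <- elec / R
  # solve the interface systems in units of the scalp radius: the raw
  # r^n / r^-(n+1) terms overflow double precision at high degree
  coef <- shell_radial_coef(n_terms, head$radii / R, head$conductivities)
  pref <- 1 / (4 * pi * head$conductivities[1])
  n_e <- nrow(elec)
  L <- matrix(0, n_e, 3L * nrow(nodes))
  ns <- seq_len(n_terms)
  for (i in seq_len(nrow(nodes))) {
    b <- sqrt(sum(nodes[i, ]^2))
    e_r <- if (b > 1e-12) nodes[i, ] / b else c(0, 0, 1)
    x <- as.numeric(e_hat %*% e_r)
    x <- pmin(1, pmax(-1, x))
    lt <- legendre_terms(x, n_terms)
    radial <- coef * (b / R)^(ns - 1) / R^2  # per degree (scaled units)
    K1 <- pref * colSums(radial * ns * lt$P)
    K2 <- pref * colSums(radial * lt$P1)
    s <- sqrt(pmax(0, 1 - x^2))
    e_t <- e_hat - outer(x, e_r)            # tangential direction per electrode
    e_t <- e_t / ifelse(s > 1e-12, s, Inf)
    block <- outer(K1, e_r) + K2 * e_t      # n_e x 3
    L[, 3L * (i - 1L) + 1:3] <- block
  }
  L <- sweep(L, 2, colMeans(L))             # average reference
  structure(list(L = L, grid = grid, head = head, n_terms = n_terms),
            class = "lead_field")
}
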