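# Fixtures and brute-force reference implementations, independent of the
# package's production code paths.

make_cube <- function(shape, lo, hi, spacing = c(1, 1, 1)) {
  a <- array(0L, shape)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  label_volume(a, voxel_geometry(spacing))
}

random_mask <- function(shape, p = 0.2, spacing = c(1, 1, 1)) {
  a <- array(as.integer(stats::runif(prod(shape)) < p), shape)
  label_volume(a, voxel_geometry(spacing))
}

# exhaustive boundary extraction: fg voxel with any 6-neighbour background
# (volume border counts as background); plain triple loop
oracle_boundary <- function(v) {
  m <- v$data; d <- dim(m); out <- NULL
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (m[i, j, k] == 0) next
    nb <- c(if (i > 1) m[i - 1, j, k] else 0L,
            if (i < d[1]) m[i + 1, j, k] else 0L,
            if (j > 1) m[i, j - 1, k] else 0L,
            if (j < d[2]) m[i, j + 1, k] else 0L,
            if (k > 1) m[i, j, k - 1] else 0L,
            if (k < d[3]) m[i, j, k + 1] else 0L)
    if (any(nb == 0L)) out <- rbind(out, c(i, j, k))
  }
  out
}

# exhaustive O(n*m) directed average surface distance
oracle_asd <- function(pv, gv) {
  bp <- oracle_boundary(pv); bg <- oracle_boundary(gv)
  sp <- pv$geometry$spacing
  bp <- sweep(bp, 2, sp, `*`); bg <- sweep(bg, 2, sp, `*`)
  mean(apply(bp, 1, function(x) min(sqrt(colSums((t(bg) - x)^2)))))
}

# exhaustive pairwise axial diameter over all voxel-center pairs
oracle_diameter <- function(idx, geometry) {
  ax <- geometry$axial_axis
  plane <- setdiff(1:3, ax)
  sp <- geometry$spacing[plane]
  best <- 0
  for (s in unique(idx[, ax])) {
    pts <- idx[idx[, ax] == s, plane, drop = FALSE]
    pts <- sweep(pts, 2, sp, `*`)
    n <- nrow(pts)
    if (n < 2) next
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      best <- max(best, sqrt(sum((pts[i, ] - pts[j, ])^2)))
    }
  }
  best
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  ev <- n * (n + 1) / 4
  mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-9)
}

# exact two-sided Mann-Whitney p by enumerating group-label assignments
oracle_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  eu <- na * length(b) / 2
  mean(abs(us - eu) >= abs(u_obs - eu) - 1e-9)
}

# small complete crossover study table built by hand
toy_study <- function(effect = 0.05, n_readers = 4, n_lesions = 6,
                      seed = 1) {
  set.seed(seed)
  grid <- expand.grid(reader = sprintf("R%d", seq_len(n_readers)),
                      lesion = seq_len(n_lesions),
                      mode = c("unassisted", "assisted"),
                      stringsAsFactors = FALSE)
  grp <- stats::setNames(rep(c("resident", "attending"),
                             length.out = n_readers),
                         sprintf("R%d", seq_len(n_readers)))
  ord <- stats::setNames(rep(c("assisted_first", "unassisted_first"),
                             length.out = n_readers),
                         sprintf("R%d", seq_len(n_readers)))
  base <- 0.85 + stats::runif(nrow(grid), 0, 0.05)
  tibble::tibble(
    reader = grid$reader,
    experience_group = unname(grp[grid$reader]),
    session_order = unname(ord[grid$reader]),
    patient = (grid$lesion - 1) %/% 2 + 1,
    lesion = grid$lesion,
    mode = grid$mode,
    session = ifelse((grid$mode == "assisted") ==
                       (ord[grid$reader] == "assisted_first"), 1L, 2L),
    time_s = ifelse(grid$mode == "assisted", 70, 120) *
      exp(stats::rnorm(nrow(grid), 0, 0.1)),
    dsc = pmin(base + ifelse(grid$mode == "assisted", effect, 0), 1),
    rvd = ifelse(grid$mode == "assisted", 9, 19) +
      stats::runif(nrow(grid), -2, 2),
    asd_mm = ifelse(grid$mode == "assisted", 0.38, 0.53) +
      stats::runif(nrow(grid), -0.05, 0.05),
    sensitivity = 0.9, specificity = 0.95, mcc = 0.9,
    n_gt = 1000L, n_pred = 1000L, n_overlap = 900L,
    gt_ml = 1, pred_ml = 1, volume_ml = 1, diameter_mm = 12
  )
}
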