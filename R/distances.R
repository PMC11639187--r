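# Nearest-neighbour distances between point clouds, used by the surface
# metric, lesion matching and the phantom's boundary perturbation.

# per-row minimum Euclidean distance from points in `a` to the set `b`;
# exact kd-tree nearest-neighbour search (eps = 0)
min_dist_to_set <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 3)
  if (!is.matrix(b)) b <- matrix(b, ncol = 3)
  if (nrow(a) == 0L) return(numeric(0))
  if (nrow(b) == 0L) return(rep(Inf, nrow(a)))
  RANN::nn2(data = b, query = a, k = 1L, eps = 0)$nn.dists[, 1]
}
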