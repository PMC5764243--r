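# fixtures built in code: small deterministic sites and variogram scaffolding

# a site from explicit pieces; stations on a line unless coords given
makeSite <- function(counts, coords = NULL, province = NULL, env = NULL) {
  n <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("S%02d", seq_len(n))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("sp%02d", seq_len(ncol(counts)))
  if (is.null(coords)) coords <- cbind(seq_len(n) - 1, 0)
  if (is.null(province)) province <- rep("A", n)
  df <- data.frame(x_km = coords[, 1], y_km = coords[, 2],
                   province = province, row.names = rownames(counts))
  if (!is.null(env)) df <- cbind(df, env)
  BenthicSite(counts, df)
}

# random counts site with a seed, for property checks
randomSite <- function(seed, n = 12, s = 6, coords = NULL, province = NULL) {
  set.seed(seed)
  counts <- matrix(rpois(n * s, 20) + 1, n, s)
  if (is.null(coords)) coords <- cbind(runif(n, 0, 3), runif(n, 0, 2))
  makeSite(counts, coords = coords, province = province)
}

# a DistanceClassing with given centers and pair counts but synthetic pair
# lists (all pointing at stations 1 and 2), for fitting fabricated variograms
fakeClassing <- function(centers, nPairs, intervalKm = NULL, hMax = NULL) {
  m <- length(centers)
  if (is.null(intervalKm))
    intervalKm <- if (m > 1) centers[2] - centers[1] else 2 * centers[1]
  edges <- c(centers - intervalKm / 2, centers[m] + intervalKm / 2)
  cutoff <- edges[m + 1]
  if (is.null(hMax)) hMax <- 2 * cutoff
  nTot <- sum(nPairs)
  nIds <- max(4, ceiling((1 + sqrt(1 + 8 * nTot)) / 2))
  pairs <- lapply(nPairs, function(k)
    matrix(rep(c(1L, 2L), each = k), ncol = 2,
           dimnames = list(NULL, c("a", "b"))))
  new("DistanceClassing", intervalKm = intervalKm, cutoffKm = cutoff,
      hMax = hMax, edges = edges, centers = centers, pairs = pairs,
      nPairs = as.integer(nPairs), sampleIds = sprintf("S%03d", seq_len(nIds)))
}

# an EmpiricalVariogram carrying fabricated gamma values
fakeEmpirical <- function(centers, gamma, nPairs = rep(50L, length(centers)),
                          s2 = NULL, hMax = NULL) {
  cl <- fakeClassing(centers, nPairs, hMax = hMax)
  if (is.null(s2)) s2 <- sum(nPairs * gamma) / sum(nPairs)
  new("EmpiricalVariogram", classing = cl, gamma = gamma,
      se = rep(0.01, length(gamma)), s2 = s2)
}

# brute-force multivariate variogram over explicit pairs: the independent
# oracle for Eq-1-style sums
bruteGamma <- function(M, pairs) {
  if (nrow(pairs) == 0) return(NA_real_)
  tot <- 0
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    tot <- tot + sum((M[a, ] - M[b, ])^2)
  }
  tot / (2 * nrow(pairs))
}
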