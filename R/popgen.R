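# Population-level statistics on haplotype collections: diversity
# indices, pairwise PhiST from two-level AMOVA, and classical MDS.

#' Construct a labelled population of haplotype profiles
#'
#' @param label population label.
#' @param profiles list of `haplotype_profile` objects sharing one
#'   covered range.
#' @param region broader geographic region label.
#' @return object of class `population_set`.
#' @export
population_set <- function(label, profiles, region = label) {
  ranges <- unique(vapply(profiles, function(p)
    paste(t(p$covered_range), collapse = ":"), character(1)))
  if (length(ranges) > 1L)
    stop("profiles in population '", label,
         "' do not share a covered range", call. = FALSE)
  structure(list(label = label, profiles = profiles, region = region),
            class = "population_set")
}

#' @export
print.population_set <- function(x, ...) {
  cat("<population_set>", x$label, "(", length(x$profiles), "profiles,",
      "region", x$region, ")\n")
  invisible(x)
}

#' Pairwise mutational distances between haplotype profiles
#'
#' The distance is the raw number of differing sites (the default
#' "pairwise difference" molecular distance): sites carried by one
#' profile and not the other count one each, and a site where both carry
#' different derived alleles counts one.
#'
#' @param profiles list of `haplotype_profile` objects.
#' @return symmetric integer matrix with zero diagonal.
#' @export
haplotype_distance_matrix <- function(profiles) {
  states <- lapply(profiles, profile_state)
  n <- length(states)
  d <- matrix(0, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- states[[i]]; b <- states[[j]]
    shared <- intersect(names(a), names(b))
    dij <- sum(a[shared] != b[shared]) +
      sum(!(names(a) %in% shared)) + sum(!(names(b) %in% shared))
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' Molecular diversity indices for one population
#'
#' Haplotype diversity `HD = n/(n-1) * (1 - sum p_k^2)` over haplotype
#' frequencies, mean number of pairwise differences
#' `M = sum_{i<j} d_ij / C(n,2)`, and nucleotide diversity `pi = M / L`
#' with `L` the covered sequence length. The caller is expected to have
#' applied the diversity exclusion policy and range restriction
#' (conventionally HVS-I, 16024-16365, L = 342).
#'
#' @param pop a [population_set()].
#' @return list (class `diversity_report`) with `HD`, `pi`, `M`, `n`, `L`.
#' @export
diversity <- function(pop) {
  n <- length(pop$profiles)
  if (n < 2L) stop("diversity needs at least 2 profiles", call. = FALSE)
  rng <- pop$profiles[[1]]$covered_range
  L <- sum(rng[, 2] - rng[, 1] + 1L)
  motifs <- vapply(pop$profiles, render_motif, character(1))
  p_k <- as.numeric(table(motifs)) / n
  HD <- n / (n - 1) * (1 - sum(p_k^2))
  d <- haplotype_distance_matrix(pop$profiles)
  M <- sum(d[upper.tri(d)]) / choose(n, 2)
  structure(list(HD = HD, pi = M / L, M = M, n = n, L = L),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf("<diversity> n=%d L=%d  HD=%.4f  M=%.3f  pi=%.5f\n",
              x$n, x$L, x$HD, x$M, x$pi))
  invisible(x)
}

#' Pairwise PhiST between two populations (two-level AMOVA)
#'
#' Sums of squares follow the `SS = sum(d^2_ij) / (2N)` convention on
#' the full pairwise-difference matrix. Variance components:
#' `s2_within = SS_within / (N - 2)` and
#' `s2_among = (SS_among/(P-1) - s2_within) / n'` with
#' `n' = (N - (n_a^2 + n_b^2)/N) / (P-1)`, P = 2.
#' `PhiST = s2_among / (s2_among + s2_within)`; negative estimates are
#' clamped to 0 unless `clamp = FALSE`.
#'
#' @param a,b [population_set()] objects with a shared covered range.
#' @param clamp clamp negative estimates to 0 (default TRUE).
#' @return PhiST estimate.
#' @export
pairwise_phist <- function(a, b, clamp = TRUE) {
  na <- length(a$profiles); nb <- length(b$profiles)
  if (na < 2L || nb < 2L)
    stop("each population needs at least 2 profiles", call. = FALSE)
  ra <- paste(t(a$profiles[[1]]$covered_range), collapse = ":")
  rb <- paste(t(b$profiles[[1]]$covered_range), collapse = ":")
  if (ra != rb) stop("populations do not share a covered range",
                     call. = FALSE)
  N <- na + nb
  d <- haplotype_distance_matrix(c(a$profiles, b$profiles))
  d2 <- d^2
  ss_total <- sum(d2) / (2 * N)
  ia <- seq_len(na); ib <- na + seq_len(nb)
  ss_within <- sum(d2[ia, ia]) / (2 * na) + sum(d2[ib, ib]) / (2 * nb)
  ss_among <- ss_total - ss_within
  s2_within <- ss_within / (N - 2)
  n_prime <- (N - (na^2 + nb^2) / N) / 1
  s2_among <- (ss_among / 1 - s2_within) / n_prime
  denom <- s2_among + s2_within
  phist <- if (denom == 0) 0 else s2_among / denom
  if (clamp) max(0, phist) else phist
}

#' Matrix of pairwise PhiST distances
#'
#' @param pops list of [population_set()] objects.
#' @param clamp passed to [pairwise_phist()].
#' @return object of class `dist_matrix`: symmetric matrix with zero
#'   diagonal, labelled by population.
#' @export
fst_matrix <- function(pops, clamp = TRUE) {
  labels <- vapply(pops, function(p) p$label, character(1))
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  if (k > 1L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    m[i, j] <- m[j, i] <- pairwise_phist(pops[[i]], pops[[j]],
                                         clamp = clamp)
  structure(m, class = c("dist_matrix", "matrix"))
}

#' Write / read a labelled square distance matrix as TSV
#'
#' @param m matrix with dimnames.
#' @param path file path.
#' @export
write_dist_matrix <- function(m, path) {
  utils::write.table(as.data.frame(unclass(m)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(m)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  structure(m, class = c("dist_matrix", "matrix"))
}

#' Classical (metric) multidimensional scaling with variance fractions
#'
#' Double-centres the squared-distance matrix
#' (`B = -1/2 * J D^2 J`), eigendecomposes it, and returns the top-`k`
#' coordinates scaled by the square root of their eigenvalues. The
#' variance fraction of dimension `j` is `lambda_j` over the sum of the
#' positive eigenvalues. A deterministic sign convention is applied: the
#' first nonzero loading of each retained axis is positive.
#'
#' @param d square symmetric distance matrix (labels in dimnames).
#' @param k number of dimensions to retain.
#' @return list (class `mds_result`) with `coordinates` (labels x k),
#'   `eigenvalues` and `variance_fraction` per retained dimension.
#' @export
classical_mds <- function(d, k = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < number of points",
                             call. = FALSE)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  lambda <- e$values
  pos_sum <- sum(lambda[lambda > 1e-12])
  if (pos_sum <= 0) {
    warning("all-zero distance matrix: variance fractions reported as 0")
    coords <- matrix(0, n, k, dimnames = list(rownames(d), NULL))
    return(structure(list(coordinates = coords, eigenvalues = lambda,
                          variance_fraction = rep(0, k)),
                     class = "mds_result"))
  }
  coords <- sapply(seq_len(k), function(j) {
    lam <- lambda[j]
    v <- e$vectors[, j]
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1]] < 0) v <- -v
    v * sqrt(max(lam, 0))
  })
  coords <- matrix(coords, n, k, dimnames = list(rownames(d), NULL))
  structure(list(coordinates = coords, eigenvalues = lambda,
                 variance_fraction = pmax(lambda[seq_len(k)], 0) / pos_sum),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat("<mds_result>", ncol(x$coordinates), "dimensions; variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}
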