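# Mantel and partial Mantel permutation tests between distance matrices
# (genetic distance vs landscape resistance, with geographic distance
# partialed out), with exhaustive enumeration for tiny label sets.

upperTri <- function(m) m[upper.tri(m)]

checkSquare <- function(...) {
  ms <- list(...)
  n <- nrow(ms[[1]])
  for (m in ms) {
    if (!is.matrix(m) || nrow(m) != ncol(m)) stop("matrices must be square")
    if (nrow(m) != n) stop("matrices must share dimensions")
    if (max(abs(m - t(m))) > 1e-9) stop("matrices must be symmetric")
    l1 <- rownames(ms[[1]]); l2 <- rownames(m)
    if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
      stop("matrix labels must match in order")
  }
  n
}

permutationsOf <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutationsOf(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Mantel permutation test
#'
#' r is the Pearson correlation of the upper-triangle entries of `A` and
#' `B`. Significance permutes rows and columns of `B` jointly; the
#' one-tailed p-value of positive association is
#' `(count(r_perm >= r_obs) + 1) / (n_perm + 1)`. When `n! <= n_perm` all
#' `n!` relabelings are enumerated exhaustively and the p-value is the exact
#' proportion `count(r_perm >= r_obs) / n!` over them (the identity
#' included).
#'
#' @param A,B square symmetric matrices with matching label order.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param alternative `"greater"` (isolation-by-resistance convention) or
#'   `"two.sided"`.
#' @return list with `r`, `p`, `n_perm`, `exhaustive`.
#' @export
mantelTest <- function(A, B, n_perm = 999L, seed = 1L,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- checkSquare(A, B)
  if (n < 4L) stop("need at least 4 labels")
  a <- upperTri(A)
  if (sd(a) == 0 || sd(upperTri(B)) == 0)
    stop("constant matrix: Mantel r undefined")
  r_obs <- cor(a, upperTri(B))
  exhaustive <- factorial(n) <= n_perm
  stat <- function(perm) cor(a, upperTri(B[perm, perm]))
  if (exhaustive) {
    perms <- permutationsOf(n)
    rs <- apply(perms, 1L, stat)
    p <- propExtreme(rs, r_obs, alternative, exact = TRUE)
    n_used <- nrow(perms)
  } else {
    rs <- withSeed(seed,
      vapply(seq_len(n_perm), function(i) stat(sample.int(n)), numeric(1)))
    p <- propExtreme(rs, r_obs, alternative, exact = FALSE)
    n_used <- n_perm
  }
  list(r = r_obs, p = p, n_perm = n_used, exhaustive = exhaustive)
}

propExtreme <- function(rs, r_obs, alternative, exact) {
  hits <- if (alternative == "greater") sum(rs >= r_obs - 1e-12)
  else sum(abs(rs) >= abs(r_obs) - 1e-12)
  if (exact) hits / length(rs) else (hits + 1) / (length(rs) + 1)
}

#' Partial Mantel test
#'
#' Correlation of `A` and `B` after both are residualized on `C` over the
#' upper triangles; significance by jointly permuting rows/columns of `B`
#' (or of `B`'s residuals with `method = "residual"`).
#'
#' @param A,B,C square symmetric matrices, same labels.
#' @param n_perm,seed,alternative as in [mantelTest()].
#' @param method `"raw"` permutes B itself; `"residual"` permutes B's
#'   residuals on C.
#' @return list with `r`, `p`, `n_perm`, `exhaustive`.
#' @export
partialMantelTest <- function(A, B, C, n_perm = 999L, seed = 1L,
                              alternative = c("greater", "two.sided"),
                              method = c("raw", "residual")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  n <- checkSquare(A, B, C)
  if (n < 4L) stop("need at least 4 labels")
  a <- upperTri(A); b <- upperTri(B); cc <- upperTri(C)
  if (sd(cc) == 0) {
    # C carries no information: reduces to the simple Mantel test
    return(mantelTest(A, B, n_perm, seed, alternative))
  }
  if (abs(cor(b, cc)) > 1 - 1e-10)
    stop("C is perfectly collinear with B")
  resid_on <- function(y, x) y - mean(y) - cov(y, x) / var(x) * (x - mean(x))
  ra <- resid_on(a, cc)
  # A collinear with C leaves no residual variance: the partial
  # association is zero by definition
  degenerate_a <- sd(ra) <= 1e-12 * max(sd(a), 1e-300)
  partial_r <- function(bvec) {
    rb <- resid_on(bvec, cc)
    if (degenerate_a || sd(rb) <= 1e-12 * max(sd(bvec), 1e-300)) return(0)
    cor(ra, rb)
  }
  r_obs <- partial_r(b)
  Bres <- B
  if (method == "residual") {
    # fold residuals back into a symmetric matrix and permute that
    Bres[upper.tri(Bres)] <- resid_on(b, cc)
    Bres <- Bres * upper.tri(Bres)
    Bres <- Bres + t(Bres)
  }
  stat <- if (method == "raw")
    function(perm) partial_r(upperTri(B[perm, perm]))
  else
    function(perm) cor(ra, upperTri(Bres[perm, perm]))
  exhaustive <- factorial(n) <= n_perm
  if (exhaustive) {
    perms <- permutationsOf(n)
    rs <- apply(perms, 1L, stat)
    p <- propExtreme(rs, r_obs, alternative, exact = TRUE)
    n_used <- nrow(perms)
  } else {
    rs <- withSeed(seed,
      vapply(seq_len(n_perm), function(i) stat(sample.int(n)), numeric(1)))
    p <- propExtreme(rs, r_obs, alternative, exact = FALSE)
    n_used <- n_perm
  }
  list(r = r_obs, p = p, n_perm = n_used, exhaustive = exhaustive)
}

#' Great-circle distance matrix between populations
#'
#' Haversine distances in km.
#'
#' @param pops data.frame `id`, `lon`, `lat` with unique ids.
#' @return labelled symmetric [matrix].
#' @export
geographicDistanceMatrix <- function(pops) {
  if (anyDuplicated(pops$id)) stop("duplicate population labels")
  n <- nrow(pops)
  m <- matrix(0, n, n, dimnames = list(pops$id, pops$id))
  xy <- as.matrix(pops[, c("lon", "lat")])
  for (i in seq_len(n - 1L)) {
    d <- geosphere::distHaversine(xy[i, , drop = FALSE],
                                  xy[(i + 1L):n, , drop = FALSE]) / 1000
    m[i, (i + 1L):n] <- d
    m[(i + 1L):n, i] <- d
  }
  m
}
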