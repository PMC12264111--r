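# Pedigree-based heritability: additive relationship matrix by the tabular
# method, single-component animal-model REML on the eigenbasis of A, the
# stratified permutation null, and empirical significance.

#' Read a pedigree table
#'
#' TSV with header columns individual_id, sire_id, dam_id, generation,
#' pedigree_set. `"0"`, `""` or `NA` denote an unknown parent (founder).
#'
#' @param path file path
#' @return validated pedigree `data.frame` with NA for unknown parents
#' @export
read_pedigree <- function(path) {
  ped <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(individual_id = "character",
                                   sire_id = "character",
                                   dam_id = "character"))
  validate_pedigree(ped)
}

#' @rdname read_pedigree
#' @param ped pedigree `data.frame`
#' @export
validate_pedigree <- function(ped) {
  need <- c("individual_id", "sire_id", "dam_id", "generation",
            "pedigree_set")
  if (!all(need %in% names(ped)))
    stop("pedigree must carry columns ", paste(need, collapse = ", "))
  for (col in c("sire_id", "dam_id")) {
    v <- as.character(ped[[col]])
    v[v %in% c("0", "")] <- NA_character_
    ped[[col]] <- v
  }
  if (anyDuplicated(ped$individual_id)) stop("individual ids not unique")
  known <- ped$individual_id
  for (col in c("sire_id", "dam_id")) {
    bad <- !is.na(ped[[col]]) & !(ped[[col]] %in% known)
    if (any(bad))
      stop("unknown parent id not declared as founder: ",
           ped[[col]][bad][1])
  }
  gen <- ped$generation[match(ped$individual_id, ped$individual_id)]
  for (col in c("sire_id", "dam_id")) {
    pg <- ped$generation[match(ped[[col]], ped$individual_id)]
    bad <- !is.na(pg) & pg >= ped$generation
    if (any(bad))
      stop("parent does not precede offspring in generation: ",
           ped$individual_id[bad][1])
  }
  ped
}

#' Additive relationship matrix by the tabular method
#'
#' Individuals are processed parents-first (by generation). For individual
#' i with parents s, d: `A[i,i] = 1 + 0.5 * A[s,d]` (terms with unknown
#' parents are 0) and `A[i,j] = 0.5 * (A[j,s] + A[j,d])` for previously
#' processed j. The diagonal is 1 plus the inbreeding coefficient; founders
#' have diagonal 1 and zero off-diagonals among themselves.
#'
#' @param ped pedigree as from [read_pedigree()]
#' @return symmetric numeric matrix with individual ids as dimnames
#' @export
build_relationship_matrix <- function(ped) {
  ped <- validate_pedigree(ped)
  o <- order(ped$generation)
  ids <- ped$individual_id[o]
  sire <- match(ped$sire_id[o], ids)
  dam <- match(ped$dam_id[o], ids)
  n <- length(ids)
  if (any(!is.na(sire) & sire >= seq_len(n)) ||
      any(!is.na(dam) & dam >= seq_len(n)))
    stop("cycle detected: parent not processed before offspring")
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    A[i, i] <- 1 + 0.5 * (if (!is.na(s) && !is.na(d)) A[s, d] else 0)
    if (i > 1) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) +
                     (if (!is.na(d)) A[j, d] else 0))
      A[i, j] <- aj
      A[j, i] <- aj
    }
  }
  # return in the input pedigree order
  A[ped$individual_id, ped$individual_id]
}

#' Animal-model REML heritability for one phenotype vector
#'
#' Fits `y = X beta + u + e` with `u ~ N(0, sigma_a^2 A)` and
#' `e ~ N(0, sigma_e^2 I)` by REML, profiling the likelihood over
#' `lambda = sigma_a^2 / sigma_e^2` on the eigenbasis of `A`: with
#' `A = U D U'`, the rotated model has diagonal covariance
#' `sigma_e^2 (lambda D + I)`, so for each lambda the GLS fit and
#' `sigma_e^2` have closed forms and the REML log-likelihood is a scalar
#' function optimized over `log(lambda) in [-10, 10]`.
#'
#' When `A` is (numerically) the identity with one record per individual,
#' the additive and residual components are confounded; the estimate is
#' returned with `converged = FALSE`.
#'
#' @param y phenotype values, one per recorded individual
#' @param A relationship (sub)matrix for the recorded individuals, in the
#'   order of `y`
#' @param X fixed-effect design matrix (default intercept only); pass
#'   `model.matrix(~ pedigree_set)` to absorb pedigree-set means
#' @param eig optional precomputed `eigen(A, symmetric = TRUE)`, reused
#'   across clusters and permutations for speed
#' @return list with sigma_a2, sigma_e2, h2, loglik, converged
#' @export
estimate_h2 <- function(y, A, X = NULL, eig = NULL) {
  n <- length(y)
  stopifnot(nrow(A) == n || !is.null(eig))
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- qr(X)$rank
  if (is.null(eig)) eig <- eigen(A, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  identity_like <- max(abs(A - diag(nrow(A)))) < 1e-10
  U <- eig$vectors
  ystar <- crossprod(U, y)
  Xstar <- crossprod(U, X)

  reml_ll <- function(loglam) {
    lam <- exp(loglam)
    v <- lam * d + 1
    w <- 1 / v
    XtWX <- crossprod(Xstar, Xstar * w)
    XtWy <- crossprod(Xstar, ystar * w)
    beta <- solve(XtWX, XtWy)
    r <- ystar - Xstar %*% beta
    rss <- sum(r^2 * w)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(s2) + sum(log(v)) +
              determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  }

  opt <- optimize(reml_ll, interval = c(-10, 10), maximum = TRUE,
                  tol = 1e-6)
  lam <- exp(opt$maximum)
  v <- lam * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xstar, Xstar * w)
  beta <- solve(XtWX, crossprod(Xstar, ystar * w))
  r <- ystar - Xstar %*% beta
  s2e <- sum(r^2 * w) / (n - p)
  s2a <- lam * s2e
  h2 <- min(1, max(0, s2a / (s2a + s2e)))
  # boundary estimates (log-lambda pinned at a bound) still count as
  # converged; only confounded designs are flagged
  list(sigma_a2 = s2a, sigma_e2 = s2e, h2 = h2,
       loglik = opt$objective, beta = drop(beta),
       converged = !identity_like)
}

#' Stratified permutations of individual labels
#'
#' Generates `n_perm` permutations of the individual ids, shuffling
#' uniformly at random only within each (generation, pedigree_set)
#' stratum — relationships between strata are preserved, so the null
#' breaks the phenotype/relatedness link while respecting the pedigree
#' design. Singleton strata are fixed points. Reproducible given `seed`.
#'
#' @param individuals character vector of recorded individual ids
#' @param ped pedigree providing generation and pedigree_set per id
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return list of `n_perm` permuted id vectors (same length/order frame
#'   as `individuals`)
#' @export
permute_pedigree_labels <- function(individuals, ped, n_perm = 100L,
                                    seed = 1L) {
  idx <- match(individuals, ped$individual_id)
  if (anyNA(idx)) stop("individual absent from pedigree: ",
                       individuals[is.na(idx)][1])
  stratum <- paste(ped$generation[idx], ped$pedigree_set[idx], sep = "|")
  groups <- split(seq_along(individuals), stratum)
  set.seed(seed)
  lapply(seq_len(n_perm), function(k) {
    out <- individuals
    for (g in groups)
      if (length(g) > 1) out[g] <- individuals[sample(g)]
    out
  })
}

#' Heritability with a stratified permutation null, per cluster
#'
#' For each cluster (row of `expression`), estimates heritability on the
#' true pedigree assignment and on `n_perm` stratified permutations of the
#' individual labels (the relationship matrix stays fixed; permuting the
#' phenotype-to-individual assignment breaks relatedness relative to the
#' phenotypes). The eigendecomposition of `A` is computed once and reused.
#'
#' @param expression clusters x individuals matrix; column names are
#'   individual ids present in `ped`
#' @param ped pedigree table
#' @param n_perm number of permutations
#' @param seed master seed; per-cluster streams derive from it
#' @param X optional fixed-effect design (default: intercept +
#'   pedigree_set)
#' @return list with `h2` (per-cluster estimates `data.frame`) and
#'   `permuted` (clusters x n_perm matrix of permuted h2)
#' @export
h2_permutation_test <- function(expression, ped, n_perm = 100L, seed = 1L,
                                X = NULL) {
  ids <- colnames(expression)
  A_full <- build_relationship_matrix(ped)
  A <- A_full[ids, ids]
  if (is.null(X)) {
    pset <- factor(ped$pedigree_set[match(ids, ped$individual_id)])
    X <- if (nlevels(pset) > 1) stats::model.matrix(~pset)
         else matrix(1, length(ids), 1)
  }
  eig <- eigen(A, symmetric = TRUE)
  perms <- permute_pedigree_labels(ids, ped, n_perm = n_perm, seed = seed)
  perm_idx <- lapply(perms, match, ids)

  n_cl <- nrow(expression)
  obs <- numeric(n_cl); conv <- logical(n_cl)
  pm <- matrix(NA_real_, n_cl, n_perm)
  for (i in seq_len(n_cl)) {
    y <- as.numeric(expression[i, ])
    fit <- estimate_h2(y, A, X = X, eig = eig)
    obs[i] <- fit$h2; conv[i] <- fit$converged
    for (k in seq_len(n_perm)) {
      # permuted assignment: phenotype of individual j goes to slot of the
      # permuted id; equivalent to y[perm]
      yk <- y[perm_idx[[k]]]
      pm[i, k] <- estimate_h2(yk, A, X = X, eig = eig)$h2
    }
  }
  h2df <- data.frame(cluster_id = rownames(expression), h2 = obs,
                     converged = conv, stringsAsFactors = FALSE)
  rownames(pm) <- rownames(expression)
  list(h2 = h2df, permuted = pm)
}

#' Empirical significance of heritability estimates
#'
#' Per cluster, `empirical_p = (1 + #\{permuted h2 >= observed\}) /
#' (1 + n_perm)` (add-one estimator, ties count against the observation),
#' BH-adjusted across clusters. A cluster is called significant iff
#' `padj < alpha` and `observed h2 >= h2_floor`, mirroring "genetics
#' significantly contributes to at least 50% of the variation".
#'
#' @param observed_h2 named or plain numeric vector of observed h2
#' @param permuted_h2 matrix, rows matching `observed_h2`
#' @param h2_floor minimum observed h2 to call significance
#' @param alpha adjusted-p threshold
#' @return `data.frame` with cluster_id, h2, empirical_p, padj, significant
#' @export
empirical_significance <- function(observed_h2, permuted_h2,
                                   h2_floor = 0.5, alpha = 0.05) {
  stopifnot(nrow(permuted_h2) == length(observed_h2))
  n_perm <- ncol(permuted_h2)
  p <- vapply(seq_along(observed_h2), function(i)
    (1 + sum(permuted_h2[i, ] >= observed_h2[i])) / (1 + n_perm),
    numeric(1))
  padj <- adjust_bh(p)
  ids <- if (!is.null(names(observed_h2))) names(observed_h2)
         else if (!is.null(rownames(permuted_h2))) rownames(permuted_h2)
         else sprintf("cluster%d", seq_along(observed_h2))
  data.frame(cluster_id = ids, h2 = as.numeric(observed_h2),
             empirical_p = p, padj = padj,
             significant = padj < alpha & observed_h2 >= h2_floor,
             stringsAsFactors = FALSE)
}
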