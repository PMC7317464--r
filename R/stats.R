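#' Two-sample randomization test on simulation ensembles
#'
#' Pools the two replicate vectors, relabels them `n_perm` times, and
#' compares the observed absolute difference of means against the permuted
#' ones. Two-sided, with the add-one correction:
#' `p = (1 + #(|perm diff| >= |obs diff|)) / (n_perm + 1)`.
#'
#' @param a,b Numeric replicate vectors (length >= 2 each).
#' @param n_perm Number of permutations (default 9999).
#' @return The p-value.
#' @export
permutation_test <- function(a, b, n_perm = 9999) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    abort("each ensemble needs at least 2 replicates", class = "coralnet_domain_error")
  }
  # sorting the pool makes the p-value exactly invariant to swapping a and b
  # under a common RNG state; the permutation null ignores order anyway
  pooled <- sort(c(a, b))
  if (max(pooled) == min(pooled)) return(1.0)
  obs <- abs(mean(a) - mean(b))
  na <- length(a); n <- length(pooled)
  total <- sum(pooled)
  count <- 0L
  for (i in seq_len(n_perm)) {
    sa <- sum(pooled[sample.int(n, na)])
    d <- abs(sa / na - (total - sa) / (n - na))
    if (d >= obs - 1e-12) count <- count + 1L
  }
  (1 + count) / (n_perm + 1)
}

#' Significance letter groups from pairwise p-values
#'
#' Greedy clique-cover lettering of a symmetric pairwise p-value matrix:
#' groups that share a letter are pairwise non-significant at `alpha`.
#' Deterministic given input order.
#'
#' @param p_matrix Symmetric matrix of pairwise p-values (diagonal ignored).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of letter labels, one per group (named if the
#'   matrix has dimnames).
#' @export
#' @examples
#' p <- matrix(c(1, .3, .01, .3, 1, .4, .01, .4, 1), 3, 3)
#' letter_groups(p)  # "a" "ab" "b"
letter_groups <- function(p_matrix, alpha = 0.05) {
  k <- nrow(p_matrix)
  stopifnot(ncol(p_matrix) == k)
  compat <- p_matrix > alpha
  diag(compat) <- TRUE
  cliques <- list()
  covered <- rep(FALSE, k)
  for (i in seq_len(k)) {
    if (covered[i]) next
    clique <- i
    for (j in seq_len(k)) {
      if (j != i && all(compat[j, clique])) clique <- c(clique, j)
    }
    cliques[[length(cliques) + 1]] <- sort(clique)
    covered[clique] <- TRUE
  }
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  labels <- character(k)
  for (ci in seq_along(cliques)) {
    members <- cliques[[ci]]
    labels[members] <- paste0(labels[members], letters_pool[ci])
  }
  names(labels) <- rownames(p_matrix)
  labels
}

#' Compare simulation ensembles with randomization tests
#'
#' Pairwise randomization tests between named replicate vectors (resistance
#' or R50 ensembles), with significance-letter grouping. Optionally applies
#' a Holm correction to the pairwise p-values before lettering.
#'
#' @param ensembles Named list of numeric replicate vectors, or a named
#'   list of `resistance_result` / `r50_result` objects.
#' @param alpha Significance level for the letters.
#' @param n_perm Permutations per pairwise test.
#' @param seed Seed for the permutation draws.
#' @param adjust `"none"` (default; letters encode raw pairwise outcomes)
#'   or `"holm"`.
#' @return An `ensemble_comparison` tibble: `group`, `n`, `mean`, `sd`,
#'   `letters`; the pairwise p-value matrix is in attribute `p_matrix`.
#' @export
compare_ensembles <- function(ensembles, alpha = 0.05, n_perm = 9999,
                              seed = NULL, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  vecs <- purrr::map(ensembles, function(x) {
    if (inherits(x, "resistance_result")) x$values$resistance
    else if (inherits(x, "r50_result")) x$values$r50
    else as.numeric(x)
  })
  vecs <- purrr::map(vecs, ~ .x[!is.na(.x)])
  k <- length(vecs)
  nm <- names(vecs) %||% paste0("group", seq_len(k))
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      sub <- if (is.null(seed)) NULL else substream_seed(seed, "perm", i, j)
      p[i, j] <- p[j, i] <- with_substream(sub,
        permutation_test(vecs[[i]], vecs[[j]], n_perm))
    }
  }
  p_used <- p
  if (adjust == "holm") {
    up <- upper.tri(p)
    p_used[up] <- stats::p.adjust(p[up], method = "holm")
    p_used[lower.tri(p_used)] <- t(p_used)[lower.tri(p_used)]
  }
  out <- tibble(group = nm,
                n = purrr::map_int(vecs, length),
                mean = purrr::map_dbl(vecs, mean),
                sd = purrr::map_dbl(vecs, sd),
                letters = unname(letter_groups(p_used, alpha)))
  structure(out, p_matrix = p, alpha = alpha,
            class = c("ensemble_comparison", class(out)))
}

#' @export
tidy.ensemble_comparison <- function(x, ...) as_tibble(x)
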