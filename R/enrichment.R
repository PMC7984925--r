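#' Hypergeometric upper-tail probability for over-representation
#'
#' Probability of observing `k` or more annotated genes in a random draw of
#' `n` genes from a universe of `N` genes of which `K` carry the annotation:
#' \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}. This is the
#' one-sided test behind classical gene-set over-representation analysis
#' (equivalent to one-sided Fisher's exact). All arguments are vectorized.
#'
#' @param N universe size.
#' @param K number of annotated genes in the universe.
#' @param n query size.
#' @param k observed overlap; must satisfy `0 <= k <= min(K, n)`.
#' @return upper-tail probability in `(0, 1]`.
#' @examples
#' hypergeom_p(20, 5, 5, 4)
#' @export
hypergeom_p <- function(N, K, n, k) {
  sizes <- c(length(N), length(K), length(n), length(k))
  len <- max(sizes)
  if (any(sizes != 1L & sizes != len)) stop("argument lengths must match or be 1")
  N <- rep_len(as.numeric(N), len); K <- rep_len(as.numeric(K), len)
  n <- rep_len(as.numeric(n), len); k <- rep_len(as.numeric(k), len)
  ok <- !is.na(N) & !is.na(K) & !is.na(n) & !is.na(k) &
    N >= 0 & K >= 0 & K <= N & n >= 0 & n <= N & k >= 0 & k <= pmin(K, n) &
    N == floor(N) & K == floor(K) & n == floor(n) & k == floor(k)
  if (!all(ok)) {
    stop("invalid hypergeometric parameters: need 0 <= K <= N, 0 <= n <= N, ",
         "0 <= k <= min(K, n), all integral", call. = FALSE)
  }
  # P(X >= k) = P(X > k - 1); phyper is numerically stable for large N
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR control: sort p-values ascending, multiply \eqn{p_{(i)}} by
#' \eqn{m/i}, enforce monotonicity from the largest rank downwards, cap at 1,
#' and return in the original input order.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests every set in `annotation` for over-representation in `query` with
#' [hypergeom_p()], adjusts across all tested sets with [bh_adjust()], and
#' reports the sets that overlap the query at all, ranked by overlap size
#' descending, then raw p ascending, then set id. The universe defaults to
#' the union of all annotated genes; an explicit universe can be supplied
#' instead (query genes and set members outside the universe are ignored).
#'
#' @param query character vector of gene symbols (normalized internally).
#' @param annotation a [gene_set_collection()].
#' @param universe_mode `"annotation_union"` (default) or `"explicit"`.
#' @param universe character vector, required for `universe_mode = "explicit"`
#'   (falls back to the collection's own `universe` field when present).
#' @param top_n truncate the report to this many rows; default 20.
#' @return data.frame with one row per reported set: `set_id`, `name`, `N`,
#'   `K`, `n`, `k`, `p_value`, `p_adjusted`, `overlap_genes` (comma-joined).
#'   Zero rows (with a warning) when the query hits no set.
#' @export
enrich <- function(query, annotation,
                   universe_mode = c("annotation_union", "explicit"),
                   universe = NULL, top_n = 20L) {
  stopifnot(inherits(annotation, "gene_set_collection"))
  universe_mode <- match.arg(universe_mode)
  if (length(annotation$sets) == 0L) stop("empty annotation collection", call. = FALSE)
  query <- unique(normalize_symbol(query))

  univ <- switch(universe_mode,
    annotation_union = sort(unique(unlist(annotation$sets))),
    explicit = {
      u <- if (!is.null(universe)) universe else annotation$universe
      if (is.null(u)) stop("explicit universe mode requires 'universe'", call. = FALSE)
      unique(normalize_symbol(u))
    })

  q <- intersect(query, univ)
  N <- length(univ)
  n <- length(q)
  ids <- names(annotation$sets)
  K <- integer(length(ids)); k <- integer(length(ids)); overlaps <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    members <- intersect(annotation$sets[[ids[i]]], univ)
    ov <- intersect(q, members)
    K[i] <- length(members); k[i] <- length(ov); overlaps[[i]] <- sort(ov)
  }
  p <- hypergeom_p(N, K, n, k)
  padj <- bh_adjust(p)   # adjusted over ALL tested sets, hit or not

  res <- data.frame(set_id = ids,
                    name = unname(annotation$set_names[ids]),
                    N = N, K = K, n = n, k = k,
                    p_value = p, p_adjusted = padj,
                    overlap_genes = vapply(overlaps, paste, "", collapse = ", "),
                    stringsAsFactors = FALSE)
  res <- res[res$k >= 1L, , drop = FALSE]
  if (nrow(res) == 0L) {
    warning("query overlaps no annotated set", call. = FALSE)
  }
  res <- res[order(-res$k, res$p_value, res$set_id), , drop = FALSE]
  res <- utils::head(res, max(0L, as.integer(top_n)))
  rownames(res) <- NULL
  res
}
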