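#' Roll protein domains up to their top-level parent
#'
#' Every domain id is replaced by its root ancestor in the annotation
#' hierarchy (a domain with no parent maps to itself); duplicate domains
#' within a gene collapse to a set. A cycle in the hierarchy is an error.
#'
#' @param annotations Data frame with `gene_id`, `domain_id`.
#' @param hierarchy Data frame with `child`, `parent` (rows absent for
#'   roots).
#' @return Rolled-up annotation data frame (`gene_id`, `domain_id`),
#'   de-duplicated.
#' @export
rollup_to_toplevel <- function(annotations, hierarchy) {
  parent <- stats::setNames(hierarchy$parent, hierarchy$child)
  root_of <- function(d) {
    seen <- character(0)
    while (d %in% names(parent)) {
      if (d %in% seen) stop("cycle in domain hierarchy at '", d, "'")
      seen <- c(seen, d)
      d <- parent[[d]]
    }
    d
  }
  uniq <- unique(annotations$domain_id)
  roots <- stats::setNames(vapply(uniq, root_of, character(1)), uniq)
  out <- annotations
  out$domain_id <- unname(roots[annotations$domain_id])
  unique(out)
}

#' Drop domains present in too few genes
#'
#' @param annotations Rolled-up annotation data frame.
#' @param min_genes Keep a domain only when it is annotated on at least
#'   this many distinct genes (default 10, so a domain in 9 genes is
#'   removed and one in 10 is kept).
#' @return Filtered annotation data frame.
#' @export
filter_rare_domains <- function(annotations, min_genes = 10L) {
  if (nrow(annotations) == 0L) return(annotations)
  cnt <- tapply(annotations$gene_id, annotations$domain_id,
                function(g) length(unique(g)))
  keep <- names(cnt)[cnt >= min_genes]
  out <- annotations[annotations$domain_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Log-odds enrichment test on a 2x2 table
#'
#' The statistic is the natural-log sample odds ratio
#' `ln((a*d)/(b*c))` for the table (a: CNE genes with the domain, b: CNE
#' genes without, c: background genes with, d: background genes without),
#' with the Haldane-Anscombe +0.5 correction applied to all cells only when
#' some cell is zero. The p-value is the two-sided Fisher exact probability
#' by default; a Wald normal approximation is available for comparison.
#'
#' @param a,b,c_,d Non-negative cell counts.
#' @param method `"fisher"` (default) or `"wald"`.
#' @return List with `log_odds`, `p_value`, the `table` used and `method`.
#' @export
log_odds_test <- function(a, b, c_, d, method = c("fisher", "wald")) {
  method <- match.arg(method)
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  if (a + b == 0 || c_ + d == 0) {
    stop("a margin of the contingency table is empty")
  }
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  lor <- log((cells[1] * cells[4]) / (cells[2] * cells[3]))
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  p <- if (method == "fisher") {
    stats::fisher.test(tab)$p.value
  } else {
    se <- sqrt(sum(1 / cells))
    2 * stats::pnorm(-abs(lor / se))
  }
  list(log_odds = lor, p_value = p, table = tab, method = method)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_i = min_{j>=i}(p_(j) * m / j)`, capped at 1,
#' returned in input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_correct <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Domain enrichment among CNE-associated genes
#'
#' For every domain surviving the roll-up and rarity filter, builds the
#' 2x2 table of CNE-associated genes versus the remaining background genes
#' and tests enrichment with [log_odds_test()]; q-values come from
#' [bh_correct()] across all tested domains. Results are sorted by q, then
#' by decreasing absolute log-odds.
#'
#' @param cne_genes Character vector of CNE-associated gene ids.
#' @param all_genes Character vector of all gene ids (the universe).
#' @param annotations Annotation data frame (`gene_id`, `domain_id`).
#' @param hierarchy Optional hierarchy for [rollup_to_toplevel()].
#' @param min_genes Rarity threshold (see [filter_rare_domains()]).
#' @param method Test method passed to [log_odds_test()].
#' @return Data frame with `domain_id`, `a`, `b`, `c`, `d`, `log_odds`,
#'   `p_value`, `q_value`.
#' @export
enrich_all <- function(cne_genes, all_genes, annotations, hierarchy = NULL,
                       min_genes = 10L, method = "fisher") {
  ann <- annotations
  if (!is.null(hierarchy) && nrow(hierarchy) > 0L) {
    ann <- rollup_to_toplevel(ann, hierarchy)
  }
  ann <- filter_rare_domains(ann, min_genes)
  cne_genes <- unique(cne_genes)
  bg_genes <- setdiff(unique(all_genes), cne_genes)
  doms <- sort(unique(ann$domain_id))
  if (length(doms) == 0L) {
    return(data.frame(domain_id = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      log_odds = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(doms, function(dm) {
    with_dom <- unique(ann$gene_id[ann$domain_id == dm])
    a <- sum(cne_genes %in% with_dom)
    b <- length(cne_genes) - a
    c_ <- sum(bg_genes %in% with_dom)
    d <- length(bg_genes) - c_
    t <- log_odds_test(a, b, c_, d, method = method)
    data.frame(domain_id = dm, a = a, b = b, c = c_, d = d,
               log_odds = t$log_odds, p_value = t$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_correct(out$p_value)
  out <- out[order(out$q_value, -abs(out$log_odds)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
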