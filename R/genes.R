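#' Assign elements to the gene with the nearest TSS
#'
#' Distance is measured from the closest element edge to the transcription
#' start site (zero when the TSS falls inside the element). Elements on
#' sequences that contain no genes are unassigned. Equidistant TSSs are
#' broken by the lexicographically smallest gene id, with `tie_flag` set.
#'
#' @param elements Element table with `element_id` (optional), `a_seq`,
#'   `a_start`, `a_end`.
#' @param genes Gene table with `gene_id`, `seq_id`, `tss`.
#' @return Data frame with `element_id`, `gene_id` (NA when unassigned),
#'   `distance` (bp, NA when unassigned), `tie_flag`.
#' @export
assign_nearest_tss <- function(elements, genes) {
  n <- nrow(elements)
  ids <- if ("element_id" %in% names(elements)) elements$element_id
         else sprintf("el%05d", seq_len(max(n, 0L)))
  out <- data.frame(element_id = ids,
                    gene_id = rep(NA_character_, n),
                    distance = rep(NA_integer_, n),
                    tie_flag = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  if (n == 0L || nrow(genes) == 0L) return(out)
  by_seq <- split(genes, genes$seq_id)
  for (i in seq_len(n)) {
    g <- by_seq[[elements$a_seq[i]]]
    if (is.null(g) || nrow(g) == 0L) next
    s <- elements$a_start[i]
    e <- elements$a_end[i]
    d <- ifelse(g$tss >= s & g$tss <= e, 0L,
                pmin(abs(g$tss - s), abs(g$tss - e)))
    dmin <- min(d)
    cand <- g$gene_id[d == dmin]
    out$gene_id[i] <- min(cand)  # lexicographic tie-break
    out$distance[i] <- as.integer(dmin)
    out$tie_flag[i] <- length(cand) > 1L
  }
  out
}

#' Per-gene association statistics
#'
#' @param assignments Output of [assign_nearest_tss()].
#' @return List with `n_assigned` (elements with a gene), `n_unassigned`,
#'   `n_genes` (distinct associated genes) and `mean_per_gene`
#'   (`n_assigned / n_genes`, reported to one decimal).
#' @export
per_gene_stats <- function(assignments) {
  assigned <- !is.na(assignments$gene_id)
  n_assigned <- sum(assigned)
  n_genes <- length(unique(assignments$gene_id[assigned]))
  if (n_genes == 0L) stop("no associated genes; mean per gene undefined")
  list(n_assigned = n_assigned,
       n_unassigned = sum(!assigned),
       n_genes = n_genes,
       mean_per_gene = round(n_assigned / n_genes, 1))
}

#' Cross-reference CNE-associated gene sets through orthology
#'
#' Reports species-A CNE-associated genes having at least one ortholog in
#' the species-B CNE-associated gene set. The orthology table may be
#' many-to-many; one A gene can map to several B genes, so the two sides of
#' the shared set can differ in size.
#'
#' @param a_genes Character vector of species-A CNE-associated gene ids.
#' @param b_cne_genes Character vector of species-B CNE-associated gene ids.
#' @param orthology Data frame with columns `gene_a`, `gene_b`.
#' @param a_universe,b_universe Optional id universes; orthology rows
#'   referencing unknown ids are skipped with a warning.
#' @return List with `pairs` (gene_a, gene_b rows in the shared set),
#'   `n_a` and `n_b` (distinct genes on each side).
#' @export
shared_cne_genes <- function(a_genes, b_cne_genes, orthology,
                             a_universe = NULL, b_universe = NULL) {
  orth <- orthology
  if (!is.null(a_universe) || !is.null(b_universe)) {
    bad <- rep(FALSE, nrow(orth))
    if (!is.null(a_universe)) bad <- bad | !(orth$gene_a %in% a_universe)
    if (!is.null(b_universe)) bad <- bad | !(orth$gene_b %in% b_universe)
    if (any(bad)) {
      warning(sum(bad), " orthology row(s) reference unknown ids; skipped")
      orth <- orth[!bad, , drop = FALSE]
    }
  }
  pairs <- orth[orth$gene_a %in% a_genes & orth$gene_b %in% b_cne_genes, ,
                drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       n_a = length(unique(pairs$gene_a)),
       n_b = length(unique(pairs$gene_b)))
}
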