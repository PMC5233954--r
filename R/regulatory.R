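#' Flag rewired edges as regulatory (TF -> TG with differentially expressed target)
#'
#' An undirected rewired edge \{a, b\} is regulatory if the directed pair
#' (a -> b) or (b -> a) is present in the background regulatory network and
#' the target gene is significantly differentially expressed
#' (`adj_p <= de_alpha`; additionally `logFC > 0` when `de_mode = "up"`).
#' Both directions may hold for mutual TFs, in which case both annotations
#' are recorded.
#'
#' @param net A `rewired_network` from [build_rewired_network()].
#' @param grn Regulatory network data.frame with columns `tf` and `tg`, as
#'   from [read_regulatory_network()].
#' @param de Differential-expression table with columns `gene`, `logFC`,
#'   `adj_p`; defaults to the table carried by `net`.
#' @param de_alpha FDR threshold on target differential expression
#'   (default 0.05).
#' @param de_mode `"any"` (default: significant DE in either direction) or
#'   `"up"` (significantly up-regulated targets only).
#' @return An object of class `regulatory_rewired`: a list with `edges` (a
#'   data.frame with one row per directed regulatory annotation: `gene_i`,
#'   `gene_j`, `tf`, `tg`, `tg_logFC`, `tg_adj_p`, `delta`) and `targets`
#'   (per-TG summary: `tg`, `n_edges`, `logFC`, `adj_p`, `tfs`).
#' @export
annotate_regulatory <- function(net, grn, de = net$de, de_alpha = 0.05,
                                de_mode = c("any", "up")) {
  de_mode <- match.arg(de_mode)
  stopifnot(inherits(net, "rewired_network"))
  if (!all(c("tf", "tg") %in% names(grn))) {
    stop("grn must have columns 'tf' and 'tg'")
  }
  edges <- net$edges
  empty <- data.frame(gene_i = character(), gene_j = character(),
                      tf = character(), tg = character(),
                      tg_logFC = numeric(), tg_adj_p = numeric(),
                      delta = numeric(), stringsAsFactors = FALSE)
  if (nrow(edges) == 0L || nrow(grn) == 0L) {
    return(new_regulatory_rewired(empty))
  }
  grn_key <- paste(grn$tf, grn$tg, sep = "\r")
  hit <- function(tf, tg) paste(tf, tg, sep = "\r") %in% grn_key
  fwd <- hit(edges$gene_i, edges$gene_j)  # gene_i regulates gene_j
  rev <- hit(edges$gene_j, edges$gene_i)  # gene_j regulates gene_i
  ann <- rbind(
    data.frame(gene_i = edges$gene_i[fwd], gene_j = edges$gene_j[fwd],
               tf = edges$gene_i[fwd], tg = edges$gene_j[fwd],
               delta = edges$delta[fwd], stringsAsFactors = FALSE),
    data.frame(gene_i = edges$gene_i[rev], gene_j = edges$gene_j[rev],
               tf = edges$gene_j[rev], tg = edges$gene_i[rev],
               delta = edges$delta[rev], stringsAsFactors = FALSE)
  )
  if (nrow(ann) == 0L) return(new_regulatory_rewired(empty))
  idx <- match(ann$tg, de$gene)
  ann$tg_logFC <- de$logFC[idx]
  ann$tg_adj_p <- de$adj_p[idx]
  ok <- !is.na(ann$tg_adj_p) & ann$tg_adj_p <= de_alpha
  if (de_mode == "up") ok <- ok & ann$tg_logFC > 0
  ann <- ann[ok, c("gene_i", "gene_j", "tf", "tg", "tg_logFC", "tg_adj_p",
                   "delta"), drop = FALSE]
  rownames(ann) <- NULL
  new_regulatory_rewired(ann)
}

new_regulatory_rewired <- function(edges) {
  targets <- if (nrow(edges)) {
    agg <- split(edges, edges$tg)
    data.frame(tg = names(agg),
               n_edges = vapply(agg, nrow, integer(1L)),
               logFC = vapply(agg, function(d) d$tg_logFC[1L], numeric(1L)),
               adj_p = vapply(agg, function(d) d$tg_adj_p[1L], numeric(1L)),
               tfs = vapply(agg, function(d)
                 paste(sort(unique(d$tf)), collapse = ","), character(1L)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(tg = character(), n_edges = integer(), logFC = numeric(),
               adj_p = numeric(), tfs = character(), stringsAsFactors = FALSE)
  }
  structure(list(edges = edges, targets = targets),
            class = "regulatory_rewired")
}

#' @export
print.regulatory_rewired <- function(x, ...) {
  cat("Regulatory rewired edge set\n",
      "  annotations: ", nrow(x$edges), "\n",
      "  distinct targets: ", nrow(x$targets), "\n", sep = "")
  invisible(x)
}
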