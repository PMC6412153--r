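# Intersection of DE results with user-supplied gene lists (pain databases,
# neural-proportion scores) and final report assembly. Annotation is purely
# additive: it never changes a DE call.

#' Annotate DE results with gene-list membership
#'
#' Adds one logical membership column per gene list (`in_<name>`) to the DE
#' table, matching symbols exactly after uppercasing (no alias resolution).
#' The attached `"summary"` attribute counts members per list among all DE
#' calls and within each call category, with the fraction of called genes
#' covered.
#'
#' @param de DE result data.frame from [run_de()].
#' @param lists a single [gene_list()] or a list of them.
#' @param annotation optional annotation mapping `gene_id` to `symbol`;
#'   without it, gene ids are used as symbols directly.
#' @return The DE data.frame with membership columns and a `"summary"`
#'   attribute (data.frame: list, call, members, called, fraction).
#' @export
intersect_gene_lists <- function(de, lists, annotation = NULL) {
  stopifnot(is.data.frame(de), "gene_id" %in% names(de))
  if (inherits(lists, "gene_list")) lists <- list(lists)
  stopifnot(all(vapply(lists, inherits, logical(1L), "gene_list")))
  symbols <- toupper(.de_symbols(de, annotation))
  called <- de$call != "none"
  summaries <- list()
  for (gl in lists) {
    col <- paste0("in_", gsub("[^A-Za-z0-9]+", "_", gl$name))
    de[[col]] <- symbols %in% gl$symbols
    for (grp in c("any", setdiff(unique(de$call), "none"))) {
      sel <- if (grp == "any") called else de$call == grp
      summaries[[length(summaries) + 1L]] <- data.frame(
        list = gl$name, call = grp,
        members = sum(de[[col]] & sel), called = sum(sel),
        fraction = if (sum(sel) > 0) sum(de[[col]] & sel) / sum(sel) else 0,
        stringsAsFactors = FALSE)
    }
  }
  attr(de, "summary") <- do.call(rbind, summaries)
  de
}

.de_symbols <- function(de, annotation = NULL) {
  if (is.null(annotation)) return(de$gene_id)
  idx <- match(de$gene_id, annotation$gene_id)
  ifelse(is.na(idx), de$gene_id, annotation$symbol[idx])
}

#' Filter DE genes by a scored gene list
#'
#' Retains the DE-called genes whose score in a scored list (e.g. a neural
#' proportion score in \[0, 1\]) is at or above the threshold. Listed genes
#' without a score are excluded with a warning.
#'
#' @param de DE result data.frame.
#' @param scored_list a [gene_list()] carrying scores.
#' @param threshold minimum score (default 0.5).
#' @param annotation optional gene_id-to-symbol map, as in
#'   [intersect_gene_lists()].
#' @return The subset of DE rows (called genes only) passing the score
#'   threshold, with a `score` column appended.
#' @export
score_filter <- function(de, scored_list, threshold = 0.5,
                         annotation = NULL) {
  stopifnot(inherits(scored_list, "gene_list"))
  if (is.null(scored_list$scores)) {
    stop("gene list '", scored_list$name, "' carries no scores")
  }
  symbols <- toupper(.de_symbols(de, annotation))
  called <- de[de$call != "none", , drop = FALSE]
  called_symbols <- symbols[de$call != "none"]
  score <- scored_list$scores[called_symbols]
  listed <- called_symbols %in% scored_list$symbols
  if (any(listed & is.na(score))) {
    warning(sum(listed & is.na(score)),
            " listed gene(s) without a score excluded")
  }
  keep <- !is.na(score) & score >= threshold
  out <- called[keep, , drop = FALSE]
  out$score <- unname(score[keep])
  out
}

#' Assemble the master report table
#'
#' Joins the DE results with the entropy table, optional gene-list
#' annotations and, for synthetic runs, the ground-truth labels. The report
#' never alters DE calls; its per-category counts always equal the call
#' partition of the DE table. With truth available a confusion summary
#' (call vs truth class) is attached.
#'
#' @param de DE result data.frame over all tested genes (possibly already
#'   annotated by [intersect_gene_lists()]).
#' @param entropy optional data.frame with `gene_id` and entropy/flag
#'   columns covering every tested gene.
#' @param truth optional truth table from [generate_cohort()].
#' @return The master data.frame of called genes, with attributes
#'   `"counts"` (call partition over all tested genes, whose category sizes
#'   always equal those of `de`) and, if truth was given, `"confusion"`
#'   (call x truth class table over all tested genes).
#' @export
build_report <- function(de, entropy = NULL, truth = NULL) {
  stopifnot(is.data.frame(de), "gene_id" %in% names(de),
            "call" %in% names(de))
  counts <- table(factor(de$call,
                         levels = c("none", "male_50", "female_50",
                                    "male_75", "female_75")))
  confusion <- NULL
  if (!is.null(truth)) {
    stopifnot(all(c("gene_id", "class") %in% names(truth)))
    if (!all(de$gene_id %in% truth$gene_id)) {
      stop("truth table does not cover all tested genes")
    }
    confusion <- table(call = de$call,
                       truth = truth$class[match(de$gene_id,
                                                 truth$gene_id)])
  }
  report <- de[de$call != "none", , drop = FALSE]
  if (!is.null(entropy)) {
    stopifnot("gene_id" %in% names(entropy))
    if (!all(de$gene_id %in% entropy$gene_id)) {
      stop("entropy table does not cover all tested genes")
    }
    idx <- match(report$gene_id, entropy$gene_id)
    for (col in setdiff(names(entropy), "gene_id")) {
      report[[paste0("entropy_", col)]] <- entropy[[col]][idx]
    }
  }
  if (!is.null(truth)) {
    idx <- match(report$gene_id, truth$gene_id)
    report$truth_class <- truth$class[idx]
    report$truth_direction <- truth$direction[idx]
    attr(report, "confusion") <- confusion
  }
  rownames(report) <- NULL
  attr(report, "counts") <- counts
  message("DE call counts: ",
          paste(names(counts), as.integer(counts), sep = "=",
                collapse = ", "))
  report
}
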