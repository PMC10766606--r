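# Proximity-proteome triage: control exclusion, replicate consensus,
# GO partitioning, cytoskeletal-interactor classification, and
# soluble-neuropil overlap.
#
# Presence is purely binary: a protein detected in any control at any
# intensity is excluded from all experiment tables, and intensities are
# never used in any filtering decision.

#' Protein-level replicate table
#'
#' One mass-spectrometry sample: protein identifiers with intensities.
#' Identifiers are matched case-insensitively and must be unique within a
#' table.
#'
#' @param sample_id sample label.
#' @param role `"experiment"` or `"control"`.
#' @param protein_id character vector of protein/gene identifiers.
#' @param intensity non-negative intensities (`NA` allowed for
#'   detected-at-trace entries).
#' @return a `replicate_table` (data.frame with `protein_id`, `intensity`
#'   columns and `sample_id`/`role` attributes).
#' @export
replicate_table <- function(sample_id, role = c("experiment", "control"),
                            protein_id, intensity = rep(NA_real_, length(protein_id))) {
  role <- match.arg(role)
  protein_id <- as.character(protein_id)
  if (length(protein_id) != length(intensity))
    stop("protein_id and intensity lengths differ")
  if (any(!nzchar(protein_id))) stop("empty protein_id")
  if (anyDuplicated(tolower(protein_id)))
    stop("duplicate protein_id within table '", sample_id, "'")
  if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  structure(data.frame(protein_id = protein_id,
                       intensity = as.numeric(intensity),
                       stringsAsFactors = FALSE),
            sample_id = as.character(sample_id), role = role,
            class = c("replicate_table", "data.frame"))
}

table_ids <- function(tab) tolower(tab$protein_id)

#' Annotation database snapshot
#'
#' Static snapshot of GO term membership, cytoskeletal interactor sets,
#' mRNA-binder exclusions, and iBAQ-like abundances used by the filter
#' cascade. Supplied as fixed inputs (never queried live) so results are
#' reproducible against a stated database version.
#'
#' @param go_mito,go_er,go_membrane protein IDs carrying the GO cellular
#'   component annotations "mitochondrion", "endoplasmic reticulum",
#'   "membrane".
#' @param actin_interactors,tubulin_interactors interactor sets (e.g.
#'   BioGRID hits for Actb / Tuba1a).
#' @param mrna_binder_exclusions proteins whose actin-interactor status is
#'   an mRNA-binding artefact and must be voided.
#' @param abundance named numeric vector, protein ID -> log2 iBAQ-like
#'   abundance (the soluble neuropil reference proteome).
#' @return an `annotation_db`.
#' @export
annotation_db <- function(go_mito = character(0), go_er = character(0),
                          go_membrane = character(0),
                          actin_interactors = character(0),
                          tubulin_interactors = character(0),
                          mrna_binder_exclusions = character(0),
                          abundance = numeric(0)) {
  chk <- function(x, nm) {
    x <- as.character(x)
    if (any(!nzchar(x))) stop("empty ID in ", nm)
    unique(tolower(x))
  }
  if (length(abundance) && (is.null(names(abundance)) ||
                            any(!is.finite(abundance))))
    stop("abundance must be a named finite numeric vector")
  ab <- as.numeric(abundance)
  names(ab) <- tolower(names(abundance))
  structure(list(go_mito = chk(go_mito, "go_mito"),
                 go_er = chk(go_er, "go_er"),
                 go_membrane = chk(go_membrane, "go_membrane"),
                 actin_interactors = chk(actin_interactors, "actin_interactors"),
                 tubulin_interactors = chk(tubulin_interactors, "tubulin_interactors"),
                 mrna_binder_exclusions = chk(mrna_binder_exclusions,
                                              "mrna_binder_exclusions"),
                 abundance = ab),
            class = "annotation_db")
}

#' Remove control-detected proteins from experiment tables
#'
#' Every protein present in any control table - at any intensity,
#' including trace detections - is removed from every experiment table.
#' Remaining intensities are untouched.
#'
#' @param experiments list of experiment [replicate_table]s.
#' @param controls list of control [replicate_table]s.
#' @return list of filtered [replicate_table]s.
#' @export
subtract_controls <- function(experiments, controls) {
  if (!length(experiments)) stop("need at least one experiment table")
  if (!length(controls)) stop("need at least one control table")
  lapply(c(experiments, controls), function(t) {
    if (!inherits(t, "replicate_table")) stop("inputs must be replicate_table")
  })
  ctrl_ids <- unique(unlist(lapply(controls, table_ids)))
  lapply(experiments, function(tab) {
    keep <- !(table_ids(tab) %in% ctrl_ids)
    out <- tab[keep, , drop = FALSE]
    attributes(out)[c("sample_id", "role")] <-
      attributes(tab)[c("sample_id", "role")]
    class(out) <- class(tab)
    rownames(out) <- NULL
    out
  })
}

#' Replicate-consensus protein set
#'
#' Proteins present in at least `min_replicates` of the supplied tables.
#'
#' @param tables list of [replicate_table]s.
#' @param min_replicates minimum number of tables a protein must appear in.
#' @return sorted character vector of protein IDs (lower-cased fold).
#' @export
consolidate_replicates <- function(tables, min_replicates = 2) {
  stopifnot(length(tables) >= 1, min_replicates >= 1)
  counts <- table(unlist(lapply(tables, table_ids)))
  sort(names(counts)[counts >= min_replicates])
}

#' Partition a protein set by a GO annotation term
#'
#' @param consensus character vector of protein IDs.
#' @param db an [annotation_db].
#' @param term `"mito"` or `"er"`.
#' @return list with `annotated` and `non_annotated` (disjoint, union =
#'   `consensus`).
#' @export
partition_by_go <- function(consensus, db, term = c("mito", "er")) {
  term <- match.arg(term)
  stopifnot(inherits(db, "annotation_db"))
  consensus <- tolower(as.character(consensus))
  ref <- if (term == "mito") db$go_mito else db$go_er
  list(annotated = sort(intersect(consensus, ref)),
       non_annotated = sort(setdiff(consensus, ref)))
}

#' Classify candidate proteins by cytoskeletal interactor membership
#'
#' Labels each candidate `actin_only`, `tubulin_only`, `both` or
#' `neither`, where effective actin membership is the actin interactor
#' set minus the mRNA-binder exclusion list (proteins whose reported
#' actin interaction reflects binding to actin mRNA, not the protein).
#'
#' @param candidates character vector of protein IDs.
#' @param db an [annotation_db].
#' @return named character vector (candidate -> label), with a `counts`
#'   attribute tabulating the four labels.
#' @export
classify_interactors <- function(candidates, db) {
  stopifnot(inherits(db, "annotation_db"))
  candidates <- sort(tolower(as.character(candidates)))
  actin_eff <- setdiff(db$actin_interactors, db$mrna_binder_exclusions)
  in_a <- candidates %in% actin_eff
  in_t <- candidates %in% db$tubulin_interactors
  lab <- character(length(candidates))
  lab[in_a & in_t] <- "both"
  lab[in_a & !in_t] <- "actin_only"
  lab[!in_a & in_t] <- "tubulin_only"
  lab[!in_a & !in_t] <- "neither"
  out <- setNames(lab, candidates)
  cnt <- vapply(c("actin_only", "tubulin_only", "both", "neither"),
                function(l) sum(lab == l), 0L)
  attr(out, "counts") <- cnt
  out
}

#' Overlap with the most abundant soluble neuropil proteins
#'
#' The soluble reference set is the abundance table minus GO
#' "membrane"-annotated proteins; the report gives the overlap of the
#' consensus with the `top_n` most abundant soluble proteins and with the
#' whole soluble set, each with its percentage of the consensus rounded to
#' integer percent. Abundance ties at the `top_n` boundary are resolved by
#' including all proteins tied with the rank-`top_n` value.
#'
#' @param consensus character vector of protein IDs.
#' @param db an [annotation_db] with a non-empty abundance table.
#' @param top_n number of most-abundant soluble proteins to consider.
#' @return list with `top_overlap`, `all_overlap` (ID vectors) and
#'   `counts` (named list label -> c(count, percentage)).
#' @export
soluble_overlap <- function(consensus, db, top_n = 200) {
  stopifnot(inherits(db, "annotation_db"), top_n >= 1)
  consensus <- tolower(as.character(consensus))
  soluble <- setdiff(names(db$abundance), db$go_membrane)
  ab <- db$abundance[soluble]
  if (top_n > length(soluble)) {
    warning("top_n exceeds soluble set size (", length(soluble),
            "); using all soluble proteins")
    top <- soluble
  } else {
    cut <- sort(ab, decreasing = TRUE)[top_n]
    top <- names(ab)[ab >= cut]      # ties at the boundary kept
  }
  pct <- function(k) if (length(consensus)) round(100 * k / length(consensus)) else 0
  top_ov <- sort(intersect(consensus, top))
  all_ov <- sort(intersect(consensus, soluble))
  list(top_overlap = top_ov, all_overlap = all_ov,
       counts = list(top = c(count = length(top_ov), percentage = pct(length(top_ov))),
                     all = c(count = length(all_ov), percentage = pct(length(all_ov)))))
}

#' Run the full proteome filter cascade
#'
#' Composes control subtraction, replicate consensus, GO partitioning
#' (mitochondrion and endoplasmic reticulum), interactor classification
#' and (when the database carries abundances) the soluble-proteome
#' overlap, mirroring the triage flowchart of a proximity-labeling
#' proteomics screen.
#'
#' @param experiments list of experiment [replicate_table]s.
#' @param controls list of control [replicate_table]s.
#' @param db an [annotation_db].
#' @param min_replicates replicate-consensus threshold.
#' @param top_n soluble-overlap rank cutoff.
#' @return a `filter_report`: `consensus_set`, `mito_annotated`,
#'   `non_annotated`, `er_annotated`, `classification`, `overlap_counts`.
#' @export
run_filter_cascade <- function(experiments, controls, db,
                               min_replicates = 2, top_n = 200) {
  filtered <- subtract_controls(experiments, controls)
  consensus <- consolidate_replicates(filtered, min_replicates)
  go_m <- partition_by_go(consensus, db, "mito")
  go_e <- partition_by_go(consensus, db, "er")
  cls <- classify_interactors(consensus, db)
  ov <- if (length(db$abundance)) soluble_overlap(consensus, db, top_n) else NULL
  structure(list(consensus_set = consensus,
                 mito_annotated = go_m$annotated,
                 non_annotated = go_m$non_annotated,
                 er_annotated = go_e$annotated,
                 classification = cls,
                 overlap_counts = if (is.null(ov)) list() else ov$counts,
                 soluble_overlap = ov,
                 min_replicates = min_replicates),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat("  consensus proteins (>= ", x$min_replicates, " replicates, controls excluded): ",
      length(x$consensus_set), "\n", sep = "")
  cat("  GO 'mitochondrion' annotated:", length(x$mito_annotated),
      " | not annotated:", length(x$non_annotated), "\n")
  cat("  GO 'endoplasmic reticulum' annotated:", length(x$er_annotated), "\n")
  cnt <- attr(x$classification, "counts")
  if (!is.null(cnt))
    cat("  interactors - actin only:", cnt[["actin_only"]],
        " tubulin only:", cnt[["tubulin_only"]],
        " both:", cnt[["both"]], "\n")
  if (length(x$overlap_counts)) {
    t <- x$overlap_counts$top; a <- x$overlap_counts$all
    cat("  soluble neuropil overlap: top ", t[["count"]], " (", t[["percentage"]],
        "%), all ", a[["count"]], " (", a[["percentage"]], "%)\n", sep = "")
  }
  invisible(x)
}
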