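# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately use plain loops and base set
# algebra, not the package's own code paths.

# Voxel-count colocalization oracle: percentage of mito voxels also in
# the actin mask, by direct enumeration.
oracle_overlap_pct <- function(mito_mask, actin_mask) {
  stopifnot(identical(dim(mito_mask), dim(actin_mask)))
  n_m <- 0L; n_o <- 0L
  m <- as.vector(mito_mask); a <- as.vector(actin_mask)
  for (i in seq_along(m)) {
    if (m[i]) {
      n_m <- n_m + 1L
      if (a[i]) n_o <- n_o + 1L
    }
  }
  100 * n_o / n_m
}

# Proteome cascade oracle: control exclusion, presence counting, GO
# partitioning, interactor classification, soluble overlap - all by
# explicit enumeration over protein IDs.
oracle_cascade <- function(experiments, controls, db, min_replicates = 2,
                           top_n = 200) {
  ctrl_ids <- character(0)
  for (tab in controls) ctrl_ids <- c(ctrl_ids, tolower(tab$protein_id))
  ctrl_ids <- unique(ctrl_ids)

  counts <- new.env()
  for (tab in experiments) {
    for (p in tolower(tab$protein_id)) {
      if (p %in% ctrl_ids) next
      counts[[p]] <- if (is.null(counts[[p]])) 1L else counts[[p]] + 1L
    }
  }
  consensus <- character(0)
  for (p in ls(counts)) if (counts[[p]] >= min_replicates)
    consensus <- c(consensus, p)
  consensus <- sort(consensus)

  mito <- character(0); non <- character(0); er <- character(0)
  for (p in consensus) {
    if (p %in% db$go_mito) mito <- c(mito, p) else non <- c(non, p)
    if (p %in% db$go_er) er <- c(er, p)
  }

  cls <- character(0)
  for (p in consensus) {
    in_a <- (p %in% db$actin_interactors) &&
      !(p %in% db$mrna_binder_exclusions)
    in_t <- p %in% db$tubulin_interactors
    cls[p] <- if (in_a && in_t) "both" else if (in_a) "actin_only" else
      if (in_t) "tubulin_only" else "neither"
  }

  ov <- NULL
  if (length(db$abundance)) {
    soluble <- setdiff(names(db$abundance), db$go_membrane)
    ab <- db$abundance[soluble]
    if (top_n >= length(ab)) top <- soluble else {
      cutoff <- sort(ab, decreasing = TRUE)[top_n]
      top <- names(ab)[ab >= cutoff]
    }
    ov <- list(top = sort(intersect(consensus, top)),
               all = sort(intersect(consensus, soluble)))
  }
  list(consensus = consensus, mito = sort(mito), non = sort(non),
       er = sort(er), classification = cls, overlap = ov)
}

# Compare a filter_report with the oracle result.
expect_cascade_matches_oracle <- function(rep, oracle) {
  expect_identical(rep$consensus_set, oracle$consensus)
  expect_identical(rep$mito_annotated, oracle$mito)
  expect_identical(rep$non_annotated, oracle$non)
  expect_identical(rep$er_annotated, oracle$er)
  expect_identical(unname(rep$classification[oracle$consensus]),
                   unname(oracle$classification[oracle$consensus]))
  if (!is.null(oracle$overlap)) {
    expect_identical(rep$soluble_overlap$top_overlap, oracle$overlap$top)
    expect_identical(rep$soluble_overlap$all_overlap, oracle$overlap$all)
  }
}

# Random generator parameters for proteome property tests.
random_proteome_params <- function() {
  n_true <- sample(0:60, 1)
  room <- max(n_true - 4, 0)
  s <- if (room > 0) {
    c(actin_only = sample(0:min(room, 8), 1),
      tubulin_only = sample(0:2, 1), both = sample(0:3, 1))
  } else c(actin_only = 0, tubulin_only = 0, both = 0)
  while (sum(s) + 2 > n_true && sum(s) > 0) s[which.max(s)] <- s[which.max(s)] - 1
  list(n_true = n_true,
       n_control_contaminants = sample(0:30, 1),
       n_singletons = sample(0:20, 1),
       frac_go_mito = runif(1),
       interactor_structure = s,
       n_mrna_excluded = if (n_true >= sum(s) + 2) 2 else 0)
}

# Simple exponential-decay rate fit (log-linear), for photoactivation
# cross-checks.
fit_loss_rate <- function(times_min, f) {
  ok <- f > 0
  unname(-coef(lm(log(f[ok]) ~ times_min[ok]))[2])
}
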