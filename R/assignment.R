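# Tiered final subgroup assignment: consensus of the two reference-cohort
# classifiers, then curated driver fusions, then manual rescue by clear
# oncogene overexpression plus expression-profile similarity to already
# assigned samples; everything else stays unclassified.

#' Consensus of internal and external classifier predictions
#'
#' Maps the external-cohort label through the vocabulary map and returns the
#' subgroup when both classifiers agree, `NA` otherwise.
#'
#' @param pred_internal,pred_external Character vectors of predicted labels
#'   (same length, same sample order).
#' @param label_map Named character vector mapping external labels to the
#'   internal nine-subgroup vocabulary; identity entries may be omitted for
#'   labels shared verbatim.
#' @return Character vector: agreed subgroup or `NA`.
#' @export
consensus_assign <- function(pred_internal, pred_external,
                             label_map = tall_label_map()) {
  stopifnot(length(pred_internal) == length(pred_external))
  mapped <- ifelse(pred_external %in% names(label_map),
                   unname(label_map[pred_external]), pred_external)
  unknown <- setdiff(unique(mapped), c(tall_subgroups(), NA))
  if (length(unknown) > 0) {
    stop("external label(s) not in the label map: ",
         paste(unknown, collapse = ", "))
  }
  ifelse(!is.na(mapped) & mapped == pred_internal, pred_internal,
         NA_character_)
}

#' Default external-to-internal label map
#'
#' Identity on shared subgroup names plus explicit entries for vocabulary
#' differences of external reference cohorts (e.g. a plain `TAL1` or
#' `TAL1 LMO2` class maps to `TAL1/LMO`).
#'
#' @return Named character vector.
#' @export
tall_label_map <- function() {
  ids <- stats::setNames(tall_subgroups(), tall_subgroups())
  c(ids,
    "TAL1" = "TAL1/LMO", "TAL1 LMO2" = "TAL1/LMO",
    "NKX2-1" = "NKX2", "NKX2_1" = "NKX2",
    "LYL1" = "LYL1/LMO2", "LMO2_LYL1" = "LYL1/LMO2",
    "HOXA13_HOTTIP" = "HOXA13")
}

#' Subgroup implied by a sample's curated driver fusions
#'
#' @param fusion_names Character vector of fusion identifiers for one
#'   sample.
#' @param driver_map Curated fusion-to-subgroup map
#'   ([tall_driver_fusions()]).
#' @return The unique implied subgroup, or `NA` (no driver fusion, or
#'   conflicting implications — flagged with attribute `conflict = TRUE`).
#' @export
fusion_assign <- function(fusion_names, driver_map = tall_driver_fusions()) {
  implied <- unique(unname(driver_map[intersect(fusion_names,
                                                names(driver_map))]))
  if (length(implied) == 0) return(NA_character_)
  if (length(implied) > 1) {
    return(structure(NA_character_, conflict = TRUE))
  }
  implied
}

#' Manual rescue by oncogene overexpression and centroid similarity
#'
#' A sample is manually assigned to the subgroup whose oncogene panel it
#' satisfies (panel score at or above `z_threshold`) when its Spearman
#' correlation to that subgroup's expression centroid is at least
#' `min_correlation` and is the maximum over all centroids.
#'
#' @param expr_sample Named numeric vector: the sample's log2(fpkm+1)
#'   profile over the feature space.
#' @param centroids Matrix of subgroup centroids (features x subgroups).
#' @param panel_scores Named numeric vector of the sample's panel scores.
#' @param exclusion_scores Named numeric vector of the sample's exclusion
#'   scores.
#' @param min_correlation Minimum Spearman correlation (default 0.5).
#' @param z_threshold Robust-z overexpression threshold (default 3).
#' @return Subgroup label or `NA`.
#' @export
manual_assign <- function(expr_sample, centroids, panel_scores,
                          exclusion_scores = NULL,
                          min_correlation = 0.5, z_threshold = 3) {
  if (is.null(centroids) || ncol(centroids) == 0) return(NA_character_)
  ok <- !is.na(panel_scores) & panel_scores >= z_threshold
  if (!is.null(exclusion_scores)) {
    ok <- ok & exclusion_scores < z_threshold
  }
  cand <- names(panel_scores)[ok]
  cand <- intersect(cand, colnames(centroids))
  if (length(cand) == 0) return(NA_character_)
  feats <- intersect(names(expr_sample), rownames(centroids))
  cors <- apply(centroids[feats, , drop = FALSE], 2, function(cen)
    stats::cor(expr_sample[feats], cen, method = "spearman"))
  cand <- cand[order(-panel_scores[cand])]
  for (sg in cand) {
    if (!is.na(cors[sg]) && cors[sg] >= min_correlation &&
        cors[sg] >= max(cors, na.rm = TRUE) - 1e-12) {
      return(structure(sg, correlation = unname(cors[sg])))
    }
  }
  NA_character_
}

#' Tiered final subgroup assignment of a cohort
#'
#' Applies the assignment tiers in order: (1) consensus of the internal and
#' external classifier predictions; (2) curated driver fusions; (3) manual
#' rescue by clear oncogene overexpression plus Spearman similarity to the
#' centroids of already-assigned (tier 1-2) samples; (4) unclassified.
#' Each sample is assigned by the first tier that succeeds, so the tiers
#' partition the cohort.
#'
#' @param pred_internal,pred_external Data frames (`sample`, `label`) of the
#'   two classifiers' predictions.
#' @param expr Log2(fpkm+1) expression matrix (genes x samples) covering at
#'   least all predicted samples.
#' @param fusions Fusion-call data frame (`sample`, `fusion`); `NULL` skips
#'   the fusion tier.
#' @param label_map External-to-internal label map.
#' @param driver_map Curated fusion-to-subgroup map.
#' @param feature_genes Feature space for centroids and similarity (default:
#'   all rows of `expr`).
#' @param panels Oncogene panels for the manual tier.
#' @param min_correlation,z_threshold Manual-tier thresholds.
#' @return List of class `tall_assignment`: `assignments` (data frame:
#'   sample, subgroup, tier, evidence columns) and `tier_counts`.
#' @export
assign_cohort <- function(pred_internal, pred_external, expr,
                          fusions = NULL,
                          label_map = tall_label_map(),
                          driver_map = tall_driver_fusions(),
                          feature_genes = NULL,
                          panels = tall_oncogene_panels(),
                          min_correlation = 0.5, z_threshold = 3) {
  samples <- pred_internal$sample
  missing_expr <- setdiff(samples, colnames(expr))
  if (length(missing_expr) > 0) {
    stop("samples without expression data: ",
         paste(missing_expr, collapse = ", "))
  }
  ext <- stats::setNames(pred_external$label, pred_external$sample)[samples]
  int <- stats::setNames(pred_internal$label, pred_internal$sample)[samples]
  subgroup <- consensus_assign(int, ext, label_map)
  tier <- ifelse(!is.na(subgroup), "consensus", NA_character_)
  fusion_name <- rep(NA_character_, length(samples))
  correlation <- rep(NA_real_, length(samples))

  if (!is.null(fusions) && nrow(fusions) > 0) {
    by_sample <- split(fusions$fusion, fusions$sample)
    for (i in which(is.na(tier))) {
      fa <- fusion_assign(by_sample[[samples[i]]], driver_map)
      if (!is.na(fa)) {
        subgroup[i] <- fa; tier[i] <- "fusion"
        fn <- intersect(by_sample[[samples[i]]], names(driver_map))
        fusion_name[i] <- paste(fn, collapse = ";")
      }
    }
  } else {
    message("no fusion table supplied; skipping the fusion tier")
  }

  if (is.null(feature_genes)) feature_genes <- rownames(expr)
  feats <- intersect(feature_genes, rownames(expr))
  assigned <- which(!is.na(tier))
  centroids <- NULL
  if (length(assigned) > 0) {
    tab <- table(subgroup[assigned])
    usable <- names(tab)[tab >= 2]
    dropped <- setdiff(names(tab), usable)
    if (length(dropped) > 0) {
      warning("no centroid for subgroup(s) with <2 assigned samples: ",
              paste(dropped, collapse = ", "))
    }
    if (length(usable) > 0) {
      centroids <- vapply(usable, function(sg) {
        cols <- samples[assigned][subgroup[assigned] == sg]
        rowMeans(expr[feats, cols, drop = FALSE])
      }, numeric(length(feats)))
      rownames(centroids) <- feats
    }
  }
  scores <- overexpression_scores(expr[, samples, drop = FALSE], panels)
  for (i in which(is.na(tier))) {
    ma <- manual_assign(expr[feats, samples[i]], centroids,
                        scores$panel_scores[i, ],
                        scores$exclusion_scores[i, ],
                        min_correlation, z_threshold)
    if (!is.na(ma)) {
      subgroup[i] <- as.character(ma); tier[i] <- "manual"
      correlation[i] <- attr(ma, "correlation")
    }
  }
  tier[is.na(tier)] <- "unclassified"
  subgroup[tier == "unclassified"] <- "unclassified"
  assignments <- data.frame(sample = samples, subgroup = subgroup,
                            tier = factor(tier, levels = c(
                              "consensus", "fusion", "manual",
                              "unclassified")),
                            pred_internal = unname(int),
                            pred_external = unname(ext),
                            fusion = fusion_name,
                            centroid_correlation = correlation,
                            stringsAsFactors = FALSE)
  structure(list(assignments = assignments,
                 tier_counts = table(assignments$tier)),
            class = "tall_assignment")
}

#' @export
print.tall_assignment <- function(x, ...) {
  n <- nrow(x$assignments)
  cat("Tiered subgroup assignment of", n, "samples\n")
  tc <- x$tier_counts
  for (nm in names(tc)) {
    cat(sprintf("  %-12s %4d (%s%%)\n", nm, tc[[nm]],
                format_rate(tc[[nm]], n, 0)))
  }
  invisible(x)
}
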