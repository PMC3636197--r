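# ---- docking-score-weighted indication prediction ----

#' Predict disease indications for compounds
#'
#' Docking-score-weighted prediction model: the coefficient linking a
#' compound to a disease is the sum of its admissible docking scores over
#' all targets associated with that disease,
#' \deqn{C(c, d) = \sum_{t \in T(d)} s(c, t) \cdot [s(c, t) \ admissible],}
#' where an edge is admissible when its score strictly exceeds both the
#' threshold and the target's reference-ligand score (as in
#' [build_network()]). The model is additive over disjoint target sets and
#' monotone in added admissible edges. The functional form is a
#' reconstruction: published applications of this scheme report only the
#' coefficients, and this simple sum reproduces their magnitude (roughly
#' the admissible score times the number of supporting targets).
#'
#' @param edges docking score table (`compound_id`, `target_id`, `score`).
#' @param reference_scores data frame `target_id`, `ref_score`.
#' @param disease_links data frame `target_id`, `disease`; rows naming
#'   targets absent from the score table are ignored with a warning.
#' @param threshold admissibility cutoff (default 9, the stringent docking
#'   cutoff used for network construction).
#' @return data frame `compound_id`, `disease`, `coefficient`,
#'   `n_supporting_targets`, sorted by coefficient (descending), ties by
#'   compound then disease. Zero-coefficient pairs are omitted.
#' @export
predict_indications <- function(edges, reference_scores, disease_links,
                                threshold = 9) {
  stopifnot(is.data.frame(disease_links),
            all(c("target_id", "disease") %in% names(disease_links)))
  if (nrow(disease_links) == 0) stop("disease map is empty", call. = FALSE)
  disease_links <- unique(disease_links[c("target_id", "disease")])

  known <- unique(check_edges(edges)$target_id)
  unknown <- !(disease_links$target_id %in% known)
  if (any(unknown)) {
    warning(sum(unknown), " disease-map row(s) reference targets absent ",
            "from the score table and were ignored", call. = FALSE)
    disease_links <- disease_links[!unknown, , drop = FALSE]
    if (nrow(disease_links) == 0) {
      return(data.frame(compound_id = character(0), disease = character(0),
                        coefficient = numeric(0),
                        n_supporting_targets = integer(0)))
    }
  }

  adm <- admissible_edges(edges, threshold, reference_scores)
  hits <- merge(adm, disease_links, by = "target_id")
  if (nrow(hits) == 0) {
    return(data.frame(compound_id = character(0), disease = character(0),
                      coefficient = numeric(0),
                      n_supporting_targets = integer(0)))
  }
  agg <- stats::aggregate(score ~ compound_id + disease, data = hits, FUN = sum)
  nt <- stats::aggregate(target_id ~ compound_id + disease, data = hits,
                         FUN = function(v) length(unique(v)))
  out <- merge(agg, nt, by = c("compound_id", "disease"))
  names(out)[names(out) == "score"] <- "coefficient"
  names(out)[names(out) == "target_id"] <- "n_supporting_targets"
  out <- out[order(-out$coefficient, out$compound_id, out$disease), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Head of a prediction table
#'
#' First `k` rows of the stable coefficient ranking (the whole table if
#' shorter).
#'
#' @param predictions output of [predict_indications()].
#' @param k number of rows (>= 1).
#' @return data frame.
#' @export
top_predictions <- function(predictions, k) {
  stopifnot(is.data.frame(predictions), k >= 1)
  utils::head(predictions, k)
}
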