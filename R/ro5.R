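# Lipinski bounds; comparisons are strict ("less than") throughout
RO5_BOUNDS <- c(mw = 500, hba = 10, hbd = 5, alogp = 5)

#' Evaluate Lipinski's Rule of Five
#'
#' Flags each molecule against the four drug-likeness criteria: molecular
#' weight < 500 Da, hydrogen-bond acceptors < 10, donors < 5 and
#' AlogP < 5. All comparisons are strict, so a molecule at exactly a bound
#' fails that criterion.
#'
#' @param desc descriptor data frame with columns `mw`, `hba`, `hbd`,
#'   `alogp` (and optionally `id`).
#' @return data frame with per-criterion logical flags (`flag_mw`,
#'   `flag_hba`, `flag_hbd`, `flag_alogp`), `n_satisfied` (0-4),
#'   `pass_strict` (all four) and `pass_relaxed` (at least three).
#' @export
ro5_evaluate <- function(desc) {
  stopifnot(is.data.frame(desc),
            all(c("mw", "hba", "hbd", "alogp") %in% names(desc)))
  out <- data.frame(
    flag_mw = desc$mw < RO5_BOUNDS[["mw"]],
    flag_hba = desc$hba < RO5_BOUNDS[["hba"]],
    flag_hbd = desc$hbd < RO5_BOUNDS[["hbd"]],
    flag_alogp = desc$alogp < RO5_BOUNDS[["alogp"]]
  )
  out$n_satisfied <- rowSums(out)
  out$pass_strict <- out$n_satisfied == 4L
  out$pass_relaxed <- out$n_satisfied >= 3L
  if ("id" %in% names(desc)) out <- cbind(id = desc$id, out)
  out
}

#' Summarize a descriptor table
#'
#' Per-descriptor location/spread statistics plus Rule-of-Five compliance
#' categories. The `except_X` categories count molecules that satisfy the
#' other three criteria irrespective of X, so every `except_X` is at least
#' as large as `all_satisfied`.
#'
#' @param desc descriptor data frame (non-empty) with at least the columns
#'   `mw`, `hba`, `hbd`, `alogp`; all numeric columns are summarized.
#' @return list of class `np_library_summary` with elements
#'   `descriptor_stats` (mean, sd, median, min, max per descriptor),
#'   `ro5_categories` (named counts: `all_satisfied`, `except_mw`,
#'   `except_acceptors`, `except_donors`, `except_alogp`,
#'   `at_least_three`) and `n_molecules`.
#' @export
library_summary <- function(desc) {
  stopifnot(is.data.frame(desc))
  if (nrow(desc) == 0) stop("empty descriptor table", call. = FALSE)
  num <- desc[vapply(desc, is.numeric, logical(1))]
  stats_df <- data.frame(
    descriptor = names(num),
    mean = vapply(num, function(v) mean(v, na.rm = TRUE), numeric(1)),
    sd = vapply(num, function(v) stats::sd(v, na.rm = TRUE), numeric(1)),
    median = vapply(num, function(v) stats::median(v, na.rm = TRUE), numeric(1)),
    min = vapply(num, function(v) min(v, na.rm = TRUE), numeric(1)),
    max = vapply(num, function(v) max(v, na.rm = TRUE), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  r <- ro5_evaluate(desc)
  cats <- c(
    all_satisfied = sum(r$pass_strict),
    except_mw = sum(r$flag_hba & r$flag_hbd & r$flag_alogp),
    except_acceptors = sum(r$flag_mw & r$flag_hbd & r$flag_alogp),
    except_donors = sum(r$flag_mw & r$flag_hba & r$flag_alogp),
    except_alogp = sum(r$flag_mw & r$flag_hba & r$flag_hbd),
    at_least_three = sum(r$pass_relaxed)
  )
  structure(list(descriptor_stats = stats_df, ro5_categories = cats,
                 n_molecules = nrow(desc)),
            class = "np_library_summary")
}

#' @export
print.np_library_summary <- function(x, ...) {
  cat("Library summary:", x$n_molecules, "molecules\n\nDescriptor statistics:\n")
  print(x$descriptor_stats, digits = 4)
  cat("\nRule-of-Five categories:\n")
  print(x$ro5_categories)
  invisible(x)
}
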