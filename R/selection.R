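#' AIC-based backward elimination for a Cox model
#'
#' Starting from the union of mandatory and optional terms, repeatedly refits
#' the model without each currently removable optional term and removes the
#' one whose removal most decreases the AIC, stopping when no removal lowers
#' it. Mandatory terms are never removed. Marginality is honored: a main
#' effect is not removable while an interaction containing it is still in the
#' model.
#'
#' @param data Fitting data frame.
#' @param mandatory Character vector of terms kept unconditionally.
#' @param optional Character vector of candidate terms (may include
#'   interactions written as `"a:b"`).
#' @param time,event,ties Passed to [fit_cox()].
#' @return List: `terms` (retained), `aic`, `model` (final [fit_cox()] fit),
#'   `trace` (data frame of removals with the AIC after each step).
#' @export
backward_select <- function(data, mandatory, optional,
                            time = "residual_time", event = "event",
                            ties = "efron") {
  all_terms <- c(mandatory, optional)
  # candidate AICs come from coxph.fit on column subsets of one design
  # matrix (identical Efron partial likelihood, no per-fit formula overhead);
  # only the final model is refit through fit_cox
  X_full <- stats::model.matrix(stats::reformulate(all_terms), data)
  asgn <- attr(X_full, "assign")[-1]
  X_full <- X_full[, -1, drop = FALSE]
  labels <- attr(stats::terms(stats::reformulate(all_terms)), "term.labels")
  norm <- function(x) {
    vapply(strsplit(x, ":", fixed = TRUE),
           function(p) paste(sort(p), collapse = ":"), "")
  }
  lab_of <- match(norm(all_terms), norm(labels))
  if (anyNA(lab_of)) stop("cannot map term(s) to design columns")
  y <- survival::Surv(data[[time]], data[[event]])
  aic_of <- function(tms) {
    cols <- which(asgn %in% lab_of[match(tms, all_terms)])
    f <- survival::coxph.fit(X_full[, cols, drop = FALSE], y, strata = NULL,
                             offset = NULL, init = NULL,
                             control = survival::coxph.control(),
                             weights = NULL, method = ties, rownames = NULL)
    if (anyNA(f$coefficients)) return(NA_real_)
    -2 * f$loglik[2] + 2 * length(f$coefficients)
  }
  current <- all_terms
  cur_aic <- aic_of(current)
  if (is.na(cur_aic)) {
    # surfaces the aliased-column error with names
    fit_cox(data, current, time = time, event = event, ties = ties)
  }
  trace <- data.frame(removed = "(initial)", aic = cur_aic,
                      stringsAsFactors = FALSE)
  repeat {
    in_model <- intersect(optional, current)
    # main effects locked while a present interaction involves them
    inter <- grep(":", current, value = TRUE, fixed = TRUE)
    locked <- unique(unlist(strsplit(inter, ":", fixed = TRUE)))
    removable <- setdiff(in_model, setdiff(locked, inter))
    if (!length(removable)) break
    aics <- vapply(removable, function(r) aic_of(setdiff(current, r)),
                   numeric(1))
    if (all(is.na(aics)) || min(aics, na.rm = TRUE) >= cur_aic) break
    best <- which.min(aics)
    current <- setdiff(current, removable[best])
    cur_aic <- aics[best]
    trace <- rbind(trace, data.frame(removed = removable[best], aic = cur_aic))
  }
  model <- fit_cox(data, current, time = time, event = event, ties = ties)
  list(terms = current, aic = model$aic, model = model, trace = trace)
}

#' Scan the biomarker catalog for the best-AIC landmark model
#'
#' For each biomarker, attaches its baseline value (and, for landmark models,
#' its change up to the landmark) to the landmark dataset, runs
#' [backward_select()] with the biomarker terms as candidates, and records
#' the final AIC. The biomarker whose final model has the smallest AIC wins.
#' Biomarkers whose fits fail are skipped with a warning; the scan is fatal
#' only if every fit fails.
#'
#' @param data Landmark dataset: one row per patient with outcome columns and
#'   all covariate terms.
#' @param biomarker_values Long data frame `patient_id`, `biomarker`,
#'   `baseline_value`, `change` (one row per patient per biomarker). The
#'   `change` column is attached as term `bm_change` when
#'   `include_change = TRUE`.
#' @param mandatory,optional Covariate terms as in [backward_select()]
#'   (exclusive of biomarker terms, which the scan adds as `bm_baseline`
#'   and optionally `bm_change`).
#' @param include_change Attach the change term (landmark models) or only the
#'   baseline value.
#' @param time,event,ties Passed to [fit_cox()].
#' @return List of class `biomarker_scan`: `table` (biomarker, aic, retained
#'   terms), `winner` (name), `winner_fit` (the [backward_select()] result for
#'   the winner), `failed` (names of skipped biomarkers).
#' @export
biomarker_scan <- function(data, biomarker_values, mandatory, optional,
                           include_change = TRUE,
                           time = "residual_time", event = "event",
                           ties = "efron") {
  markers <- unique(biomarker_values$biomarker)
  if (!length(markers)) stop("empty biomarker catalog")
  rows <- list(); fits <- list(); failed <- character(0)
  for (bm in markers) {
    bv <- biomarker_values[biomarker_values$biomarker == bm, ]
    idx <- match(data$patient_id, bv$patient_id)
    d <- data
    d$bm_baseline <- bv$baseline_value[idx]
    bm_terms <- "bm_baseline"
    if (include_change) {
      d$bm_change <- bv$change[idx]
      bm_terms <- c(bm_terms, "bm_change")
    }
    res <- tryCatch(
      backward_select(d, mandatory, c(optional, bm_terms),
                      time = time, event = event, ties = ties),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning("biomarker ", bm, " skipped: ", conditionMessage(res))
      failed <- c(failed, bm)
      next
    }
    rows[[bm]] <- data.frame(biomarker = bm, aic = res$aic,
                             terms = paste(res$terms, collapse = ","),
                             stringsAsFactors = FALSE)
    fits[[bm]] <- res
  }
  if (!length(rows)) stop("all biomarker fits failed")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  winner <- tab$biomarker[which.min(tab$aic)]
  structure(
    list(table = tab, winner = winner, winner_fit = fits[[winner]],
         failed = failed),
    class = "biomarker_scan"
  )
}

#' @export
print.biomarker_scan <- function(x, ...) {
  cat("Biomarker AIC scan over", nrow(x$table), "candidates; winner:",
      x$winner, "\n")
  tab <- x$table[order(x$table$aic), ]
  print(data.frame(biomarker = tab$biomarker, aic = round(tab$aic, 2)),
        row.names = FALSE)
  invisible(x)
}
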