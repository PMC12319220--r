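#' Catalog of inflammatory biomarker indices
#'
#' Returns the fifteen composite indices built from six routine serum
#' markers: four inflammatory components (neutrophils, monocytes, platelets,
#' CRP) and two anti-inflammatory components (lymphocytes, albumin). Pairs
#' within the same category are multiplied; mixed pairs are divided
#' (anti-inflammatory marker in the denominator only when the inflammatory
#' marker leads, so CRP never appears in a denominator — a CRP of zero from
#' assay detection limits would make such a ratio incomputable). The
#' prognostic nutritional index (PNI) has its own formula.
#'
#' @param pni_convention `"paper"` computes PNI as
#'   `albumin + 0.005 * lymphocytes`; `"standard"` uses the conventional
#'   `10 * albumin + 0.005 * lymphocytes`.
#' @return A data frame with one row per biomarker: `name`, `kind`
#'   (`"ratio"`, `"product"` or `"pni"`), `numerator`, `denominator`
#'   (comma-separated raw marker names; empty for PNI).
#' @export
#' @examples
#' catalog <- biomarker_catalog()
#' nrow(catalog)   # 15
biomarker_catalog <- function(pni_convention = c("paper", "standard")) {
  pni_convention <- match.arg(pni_convention)
  defs <- rbind(
    data.frame(name = "NLR", kind = "ratio", numerator = "neutrophils", denominator = "lymphocytes"),
    data.frame(name = "LMR", kind = "ratio", numerator = "lymphocytes", denominator = "monocytes"),
    data.frame(name = "PLR", kind = "ratio", numerator = "platelets", denominator = "lymphocytes"),
    data.frame(name = "CAR", kind = "ratio", numerator = "crp", denominator = "albumin"),
    data.frame(name = "PNI", kind = "pni", numerator = "albumin,lymphocytes", denominator = ""),
    data.frame(name = "NAR", kind = "ratio", numerator = "neutrophils", denominator = "albumin"),
    data.frame(name = "MAR", kind = "ratio", numerator = "monocytes", denominator = "albumin"),
    data.frame(name = "PAR", kind = "ratio", numerator = "platelets", denominator = "albumin"),
    data.frame(name = "NxM", kind = "product", numerator = "neutrophils,monocytes", denominator = ""),
    data.frame(name = "NxP", kind = "product", numerator = "neutrophils,platelets", denominator = ""),
    data.frame(name = "NxC", kind = "product", numerator = "neutrophils,crp", denominator = ""),
    data.frame(name = "MxP", kind = "product", numerator = "monocytes,platelets", denominator = ""),
    data.frame(name = "MxC", kind = "product", numerator = "monocytes,crp", denominator = ""),
    data.frame(name = "PxC", kind = "product", numerator = "platelets,crp", denominator = ""),
    data.frame(name = "LxA", kind = "product", numerator = "lymphocytes,albumin", denominator = "")
  )
  attr(defs, "pni_convention") <- pni_convention
  defs
}

raw_marker_names <- function() {
  c("monocytes", "platelets", "crp", "albumin", "neutrophils", "lymphocytes")
}

split_markers <- function(x) {
  if (!nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
}

#' Compute one biomarker index from a marker panel
#'
#' @param defn One row of [biomarker_catalog()] (a data frame or list with
#'   `name`, `kind`, `numerator`, `denominator`).
#' @param panel Named list or one-row data frame holding the raw markers the
#'   definition references (units: cells per microlitre for counts, mg/dl for
#'   CRP, g/dl for albumin). Values may be vectors of equal length.
#' @param pni_convention See [biomarker_catalog()].
#' @return Numeric value(s); `NA` where an input marker is missing (`NA`).
#'   A zero denominator raises an error naming the offending marker; a zero
#'   numerator is a valid value of 0.
#' @export
#' @examples
#' cat15 <- biomarker_catalog()
#' compute_biomarker(cat15[cat15$name == "NLR", ],
#'                   list(neutrophils = 3000, lymphocytes = 1500))  # 2
compute_biomarker <- function(defn, panel, pni_convention = c("paper", "standard")) {
  pni_convention <- match.arg(pni_convention)
  defn <- as.list(defn)
  num <- split_markers(defn$numerator)
  den <- split_markers(defn$denominator)
  need <- c(num, den)
  missing_markers <- setdiff(need, names(panel))
  if (length(missing_markers)) {
    stop("marker(s) absent from panel: ", paste(missing_markers, collapse = ", "))
  }
  get <- function(m) as.numeric(panel[[m]])
  if (defn$kind == "pni") {
    alb_scale <- if (pni_convention == "standard") 10 else 1
    return(alb_scale * get("albumin") + 0.005 * get("lymphocytes"))
  }
  num_val <- Reduce(`*`, lapply(num, get))
  if (defn$kind == "product") return(num_val)
  den_val <- Reduce(`*`, lapply(den, get))
  bad <- !is.na(den_val) & den_val == 0
  if (any(bad)) {
    stop("zero denominator for biomarker ", defn$name, " (marker: ",
         paste(den, collapse = "*"), ")")
  }
  num_val / den_val
}

#' Compute all cataloged biomarkers for a long-format lab table
#'
#' @param labs Data frame with columns `patient_id`, `visit_month` and the six
#'   raw markers (`monocytes`, `platelets`, `crp`, `albumin`, `neutrophils`,
#'   `lymphocytes`).
#' @param catalog Output of [biomarker_catalog()]; defaults to the full panel.
#' @param pni_convention See [biomarker_catalog()].
#' @return Long data frame: `patient_id`, `visit_month`, `biomarker`, `value`.
#' @export
compute_biomarkers <- function(labs, catalog = biomarker_catalog(),
                               pni_convention = c("paper", "standard")) {
  pni_convention <- match.arg(pni_convention)
  stopifnot(all(c("patient_id", "visit_month") %in% names(labs)))
  out <- lapply(seq_len(nrow(catalog)), function(i) {
    data.frame(
      patient_id = labs$patient_id,
      visit_month = labs$visit_month,
      biomarker = catalog$name[i],
      value = compute_biomarker(catalog[i, ], labs, pni_convention),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$biomarker, res$patient_id, res$visit_month), ]
}

#' Last-observation-carried-forward imputation over a visit schedule
#'
#' Fills every scheduled visit up to each patient's last observed visit with
#' the most recent earlier value. The baseline (month 0) value must be
#' observed: series without it signal an exclusion error rather than being
#' silently imputed, mirroring the upstream rule that patients lacking a
#' surgery-time measurement leave the cohort.
#'
#' @param series Long data frame with `patient_id`, `visit_month`, `value`
#'   (and optionally `biomarker`); absent visits may be missing rows or `NA`
#'   values. Visits are only ever filled up to the patient's last observed
#'   visit unless `schedule` extends beyond it, in which case later scheduled
#'   visits are carried forward too (the caller restricts the schedule to the
#'   patient's follow-up).
#' @param schedule Integer vector of scheduled visit months (must start at 0).
#' @return Data frame `patient_id[, biomarker], visit_month, value, imputed`
#'   with one row per patient (x biomarker) per scheduled visit.
#' @export
#' @examples
#' x <- data.frame(patient_id = 1, visit_month = c(0, 9), value = c(50, 48))
#' locf_impute(x, c(0, 3, 6, 9, 12))$value   # 50 50 50 48 48
locf_impute <- function(series, schedule = c(0, 3, 6, 9, 12)) {
  stopifnot(is.numeric(schedule), schedule[1] == 0, !is.unsorted(schedule))
  has_bm <- "biomarker" %in% names(series)
  key <- if (has_bm) paste(series$patient_id, series$biomarker, sep = "\r")
         else as.character(series$patient_id)
  obs <- !is.na(series$value)
  s_key <- key[obs]
  s_visit <- series$visit_month[obs]
  s_value <- series$value[obs]
  o <- order(s_key, s_visit)
  s_key <- s_key[o]; s_visit <- s_visit[o]; s_value <- s_value[o]
  grp <- factor(s_key, levels = unique(s_key))
  no_obs <- setdiff(unique(key), levels(grp))
  first_idx <- which(!duplicated(grp))
  bad <- s_visit[first_idx] != 0
  if (length(no_obs) || any(bad)) {
    who <- c(no_obs, levels(grp)[bad])
    stop("no observed baseline (month 0) value for: ",
         paste(gsub("\r", "/", utils::head(who, 5)), collapse = ", "),
         "; exclude upstream")
  }
  # composite sort key (group index, visit) lets one findInterval carry the
  # last observation forward for every group at once
  big <- max(c(s_visit, schedule)) + 1
  obs_key <- (as.integer(grp) - 1) * big + s_visit
  ng <- nlevels(grp)
  gi <- rep(seq_len(ng), each = length(schedule))
  vm <- rep(schedule, ng)
  grid_key <- (gi - 1) * big + vm
  idx <- findInterval(grid_key, obs_key)
  res <- data.frame(
    patient_id = series$patient_id[obs][o][first_idx][gi],
    visit_month = vm,
    value = s_value[idx],
    imputed = !(grid_key %in% obs_key),
    stringsAsFactors = FALSE
  )
  if (has_bm) res$biomarker <- series$biomarker[obs][o][first_idx][gi]
  cols <- c("patient_id", if (has_bm) "biomarker", "visit_month", "value", "imputed")
  ord <- if (has_bm) order(res$biomarker, res$patient_id, res$visit_month)
         else order(res$patient_id, res$visit_month)
  res <- res[ord, cols]
  rownames(res) <- NULL
  res
}
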