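#' Organ-dose constraint policy for activity prescription
#'
#' The administered therapy activity is chosen so that no constraint ROI
#' exceeds `dose_limit`.  With `binding_rule = "max_over_rois"` the largest
#' coefficient among `constraint_rois` binds (safety-conservative default);
#' with `binding_rule = list(named_roi = "<roi>")` a single named ROI binds
#' regardless of the others, which reproduces planning schemes anchored to
#' one reference marrow site.
#'
#' @param dose_limit Absorbed-dose limit in Gy (default 3, the bone-marrow
#'   planning constraint).
#' @param constraint_rois ROI names under the constraint (default the three
#'   marrow ROIs).
#' @param binding_rule `"max_over_rois"` or `list(named_roi = "<name>")`.
#' @return Object of class `prescription_policy`.
#' @export
prescription_policy <- function(dose_limit = 3,
                                constraint_rois = c("marrow_spine",
                                                    "marrow_left_shoulder",
                                                    "marrow_right_shoulder"),
                                binding_rule = "max_over_rois") {
  if (dose_limit <= 0) stop("dose_limit must be > 0 Gy")
  if (length(constraint_rois) == 0) stop("constraint_rois must be non-empty")
  named <- is.list(binding_rule) && !is.null(binding_rule$named_roi)
  if (!named && !identical(binding_rule, "max_over_rois"))
    stop("binding_rule must be 'max_over_rois' or list(named_roi = ...)")
  if (named && !binding_rule$named_roi %in% constraint_rois)
    constraint_rois <- union(constraint_rois, binding_rule$named_roi)
  structure(list(dose_limit = dose_limit, constraint_rois = constraint_rois,
                 binding_rule = binding_rule),
            class = "prescription_policy")
}

#' Prescribe administered activity under an organ-dose limit
#'
#' Computes `activity = dose_limit / c_binding`, where the binding
#' coefficient is chosen by the policy, and projects the dose to every ROI in
#' the table at that activity.  Activities are reported to 3 decimals (GBq)
#' and doses to 2 decimals (Gy); the projected doses are computed from the
#' unrounded activity.
#'
#' @param coeffs `data.frame` with columns `roi` and `gy_per_gbq` (as from
#'   [dose_coefficients()] or [read_dose_coefficients()]).  ROIs with
#'   coefficient `NA` are carried through as absent organs.
#' @param policy A [prescription_policy()].
#' @return Object of class `prescription_result`: `prescribed_activity_gbq`
#'   (rounded, 3 decimals), `activity_gbq` (unrounded), `binding_roi`,
#'   `projected_doses` (data.frame `roi`, `gy_per_gbq`, `projected_gy`) and
#'   the policy.
#' @export
prescribe <- function(coeffs, policy = prescription_policy()) {
  stopifnot(is.data.frame(coeffs), all(c("roi", "gy_per_gbq") %in% names(coeffs)),
            inherits(policy, "prescription_policy"))
  have <- coeffs$roi[!is.na(coeffs$gy_per_gbq)]
  missing <- setdiff(policy$constraint_rois, have)
  named <- is.list(policy$binding_rule)
  if (named) {
    nm <- policy$binding_rule$named_roi
    if (!nm %in% have) stop("binding ROI '", nm, "' absent from the table")
    c_bind <- coeffs$gy_per_gbq[coeffs$roi == nm]
    binding <- nm
  } else {
    if (length(missing))
      stop("constraint ROI(s) absent from the table: ",
           paste(missing, collapse = ", "))
    sub <- coeffs[coeffs$roi %in% policy$constraint_rois, ]
    i <- which.max(sub$gy_per_gbq)
    c_bind <- sub$gy_per_gbq[i]
    binding <- sub$roi[i]
  }
  if (is.na(c_bind) || c_bind <= 0)
    stop("binding coefficient for '", binding, "' is not positive")
  activity <- policy$dose_limit / c_bind
  projected <- data.frame(roi = coeffs$roi, gy_per_gbq = coeffs$gy_per_gbq,
                          projected_gy = round(coeffs$gy_per_gbq * activity, 2))
  structure(list(prescribed_activity_gbq = round(activity, 3),
                 activity_gbq = activity,
                 binding_roi = binding,
                 projected_doses = projected,
                 policy = policy),
            class = "prescription_result")
}

#' @export
print.prescription_result <- function(x, ...) {
  cat(sprintf("<prescription> %.3f GBq (binding ROI %s at %.4g Gy limit)\n",
              x$prescribed_activity_gbq, x$binding_roi, x$policy$dose_limit))
  print(x$projected_doses, row.names = FALSE)
  invisible(x)
}

#' Render a prescription report table
#'
#' One row per ROI with its Gy/GBq coefficient and the projected dose at the
#' prescribed activity; absent organs (coefficient `NA`, e.g. testes in a
#' female subject) are rendered as `"-"`.
#'
#' @param result A [prescribe()] result.
#' @param path Optional CSV output path.
#' @return `data.frame` with character columns `roi`, `gy_per_gbq`,
#'   `projected_gy`; written to `path` if given.
#' @export
render_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "prescription_result"))
  pd <- result$projected_doses
  fmt <- function(x, digits) ifelse(is.na(x), "-", formatC(x, digits = digits,
                                                           format = "f"))
  tab <- data.frame(roi = pd$roi,
                    gy_per_gbq = fmt(pd$gy_per_gbq, 2),
                    projected_gy = fmt(pd$projected_gy, 2),
                    stringsAsFactors = FALSE)
  attr(tab, "prescribed_activity_gbq") <- result$prescribed_activity_gbq
  attr(tab, "binding_roi") <- result$binding_roi
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# prescribed_activity_gbq=%.3f binding_roi=%s limit_gy=%g",
                       result$prescribed_activity_gbq, result$binding_roi,
                       result$policy$dose_limit), con)
    utils::write.csv(tab, con, row.names = FALSE)
  }
  tab
}

#' Read a per-ROI dose-coefficient CSV
#'
#' Expects columns `roi` and `gy_per_gbq` (absent organs as empty or `-`),
#' and optionally `subject`, in which case `subject` filters one subject's
#' table.
#'
#' @param path CSV path.
#' @param subject Optional subject identifier to select.
#' @return `data.frame` with columns `roi`, `gy_per_gbq` (numeric, NA for
#'   absent organs).
#' @export
read_dose_coefficients <- function(path, subject = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(subject)) {
    if (!"subject" %in% names(tab)) stop("table has no subject column")
    tab <- tab[tab$subject == subject, ]
    if (nrow(tab) == 0) stop("no rows for subject '", subject, "'")
  }
  if (!all(c("roi", "gy_per_gbq") %in% names(tab)))
    stop("expected columns roi and gy_per_gbq in ", path)
  tab$gy_per_gbq <- suppressWarnings(as.numeric(ifelse(tab$gy_per_gbq %in%
                                                         c("-", ""), NA,
                                                       tab$gy_per_gbq)))
  tab[c("roi", "gy_per_gbq")]
}
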