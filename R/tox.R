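#' Load a toxicology reference table
#'
#' Builds one `tox_profile` per compound from a tabular source with columns
#' `compound_id`, `oel_value`, `oel_unit`, `oel_kind`, `iur`, `iur_unit`,
#' `source_note`. The occupational exposure limit (OEL) hierarchy follows the
#' exposure scenario: panelists inhale each presentation for a few seconds, so
#' a short-term (15 min) OEL is the appropriate reference and is retained as
#' the active limit whenever present; the 8-h time-weighted average is kept as
#' a conservative fallback for compounds that lack a short-term value (8-h
#' limits are lower, so falling back on them overstates risk, never the
#' reverse). Compounds with neither an OEL nor an inhalation unit risk (IUR)
#' are loaded but flagged unusable; they can then be reported as exclusions
#' rather than silently dropped.
#'
#' @param rows a data frame of tox records, or the path of a CSV file holding
#'   one. `oel_kind` must be `"short_term_15min"` or `"twa_8h"`; multiple rows
#'   per compound (one per OEL kind) are allowed. `iur` is the inhalation unit
#'   risk per (ug/m3) (or per (mg/m3) when `iur_unit` says so); leave empty
#'   for non-carcinogens.
#' @return an object of class `tox_table`: a named list of `tox_profile`
#'   objects with attributes `rejected` (data frame of rejected rows with a
#'   `reason` column) and `unusable` (compound ids lacking both OEL and IUR).
#' @export
load_tox_table <- function(rows) {
  if (is.character(rows) && length(rows) == 1) {
    rows <- utils::read.csv(rows, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(rows))
  required <- c("compound_id", "oel_value", "oel_unit", "oel_kind")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols) > 0) {
    stop("tox table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(rows$iur)) rows$iur <- NA_real_
  if (is.null(rows$iur_unit)) rows$iur_unit <- "per_ug_m3"
  if (is.null(rows$source_note)) rows$source_note <- ""

  rejected <- list()
  keep <- rep(TRUE, nrow(rows))
  oel_canon <- rep(NA_real_, nrow(rows))
  iur_canon <- rep(NA_real_, nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    has_oel <- !is.na(r$oel_value) && nzchar(as.character(r$oel_value))
    if (has_oel) {
      if (!is.na(r$oel_value) && r$oel_value <= 0) {
        rejected[[length(rejected) + 1]] <- cbind(r, reason = "non-positive OEL")
        keep[i] <- FALSE
        next
      }
      ok <- try(canonicalize_concentration(r$oel_value, r$oel_unit), silent = TRUE)
      if (inherits(ok, "try-error")) {
        rejected[[length(rejected) + 1]] <- cbind(r, reason = "unknown OEL unit")
        keep[i] <- FALSE
        next
      }
      if (!r$oel_kind %in% c("short_term_15min", "twa_8h")) {
        rejected[[length(rejected) + 1]] <- cbind(r, reason = "unknown oel_kind")
        keep[i] <- FALSE
        next
      }
      oel_canon[i] <- ok
    }
    if (!is.na(r$iur)) {
      if (r$iur < 0) {
        rejected[[length(rejected) + 1]] <- cbind(r, reason = "negative IUR")
        keep[i] <- FALSE
        next
      }
      iur_canon[i] <- switch(as.character(r$iur_unit),
        per_ug_m3 = r$iur,
        per_mg_m3 = r$iur / 1000,
        stop("unknown IUR unit: ", sQuote(r$iur_unit))
      )
    }
  }
  rows <- rows[keep, , drop = FALSE]
  oel_canon <- oel_canon[keep]
  iur_canon <- iur_canon[keep]

  profiles <- list()
  for (id in unique(rows$compound_id)) {
    idx <- which(rows$compound_id == id)
    sub <- rows[idx, , drop = FALSE]
    st <- idx[sub$oel_kind == "short_term_15min" & !is.na(oel_canon[idx])]
    lt <- idx[sub$oel_kind == "twa_8h" & !is.na(oel_canon[idx])]
    iur <- iur_canon[idx][!is.na(iur_canon[idx])]
    iur <- if (length(iur) > 0) iur[1] else NA_real_
    if (length(st) > 0) {
      active_value <- oel_canon[st[1]]
      active_kind <- "short_term_15min"
      fallback <- if (length(lt) > 0) oel_canon[lt[1]] else NA_real_
    } else if (length(lt) > 0) {
      active_value <- oel_canon[lt[1]]
      active_kind <- "twa_8h"
      fallback <- NA_real_
    } else {
      active_value <- NA_real_
      active_kind <- NA_character_
      fallback <- NA_real_
    }
    profiles[[id]] <- structure(
      list(
        compound_id = id,
        oel_value = active_value,    # ug/m3, active limit
        oel_kind = active_kind,
        oel_twa8h_fallback = fallback,
        iur = iur,                   # per (ug/m3); NA marks a non-carcinogen
        source_note = paste(unique(sub$source_note[nzchar(sub$source_note)]),
                            collapse = "; "),
        usable = !is.na(active_value) || !is.na(iur)
      ),
      class = "tox_profile"
    )
  }

  rejected <- if (length(rejected) > 0) {
    do.call(rbind, rejected)
  } else {
    cbind(rows[0, , drop = FALSE], reason = character(0))
  }
  unusable <- names(profiles)[!vapply(profiles, `[[`, logical(1), "usable")]
  structure(profiles, class = "tox_table",
            rejected = rejected, unusable = unusable)
}

#' @export
print.tox_table <- function(x, ...) {
  n <- length(x)
  n_oel <- sum(vapply(x, function(p) !is.na(p$oel_value), logical(1)))
  n_iur <- sum(vapply(x, function(p) !is.na(p$iur), logical(1)))
  cat("Toxicology table:", n, "compound(s);", n_oel, "with an active OEL,",
      n_iur, "carcinogen(s) with an IUR\n")
  unusable <- attr(x, "unusable")
  if (length(unusable) > 0) {
    cat("  unusable (no OEL, no IUR):", paste(unusable, collapse = ", "), "\n")
  }
  rej <- attr(x, "rejected")
  if (nrow(rej) > 0) cat("  rejected rows:", nrow(rej), "\n")
  invisible(x)
}

#' Resolve compounds against a toxicology table
#'
#' Splits a set of compound ids into those with a usable `tox_profile` and
#' those excluded (absent from the table or flagged unusable). The split is
#' total: every id lands on exactly one side, so excluded compounds can be
#' reported rather than silently dropped.
#'
#' @param tox a `tox_table`.
#' @param compound_ids character vector.
#' @return list with `resolved` (named list of profiles) and `excluded`
#'   (data frame: `compound_id`, `reason`).
#' @export
resolve_compounds <- function(tox, compound_ids) {
  stopifnot(inherits(tox, "tox_table"))
  compound_ids <- unique(compound_ids)
  resolved <- list()
  excluded <- data.frame(compound_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (id in compound_ids) {
    p <- tox[[id]]
    if (is.null(p)) {
      excluded <- rbind(excluded, data.frame(
        compound_id = id, reason = "absent from tox table"))
    } else if (!p$usable) {
      excluded <- rbind(excluded, data.frame(
        compound_id = id, reason = "no OEL and no IUR"))
    } else {
      resolved[[id]] <- p
    }
  }
  list(resolved = resolved, excluded = excluded)
}
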