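#' Threshold matrix of individual odor threshold estimates
#'
#' Dynamic olfactometry presents an odor sample to a panel at decreasing
#' dilutions; each assessor's individual threshold estimate (Z_ITE) is the
#' dilution factor at which they first (and then confirmably) perceive the
#' odor. One analysis yields a grid of Z_ITE values indexed by assessor and
#' round.
#'
#' @param values numeric matrix (assessors x rounds) or vector of positive
#'   Z_ITE dilution factors.
#' @param n_assessors,n_rounds used to shape a vector input; ignored when
#'   `values` is already a matrix.
#' @param dilution_step_factor the olfactometer's exponential dilution step
#'   (default 2: concentrations double between consecutive presentations).
#' @return an object of class `threshold_matrix`.
#' @export
threshold_matrix <- function(values, n_assessors = NULL, n_rounds = NULL,
                             dilution_step_factor = 2) {
  if (!is.matrix(values)) {
    if (!is.null(n_assessors) && !is.null(n_rounds)) {
      stopifnot(length(values) == n_assessors * n_rounds)
      values <- matrix(values, nrow = n_assessors, ncol = n_rounds)
    } else {
      values <- matrix(values, nrow = length(values), ncol = 1)
    }
  }
  if (length(values) < 1) stop("threshold matrix needs at least one entry")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("every Z_ITE must be a finite positive dilution factor")
  }
  if (!is.finite(dilution_step_factor) || dilution_step_factor <= 0) {
    stop("dilution_step_factor must be positive")
  }
  structure(values, class = c("threshold_matrix", "matrix"),
            dilution_step_factor = dilution_step_factor)
}

#' @export
print.threshold_matrix <- function(x, ...) {
  cat("Threshold matrix:", nrow(x), "assessor(s) x", ncol(x), "round(s),",
      "dilution step", attr(x, "dilution_step_factor"), "\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Read a threshold matrix from CSV
#'
#' Expects long format: `assessor_id`, `round_index`, `z_ite`.
#'
#' @param path CSV path (or data frame).
#' @param dilution_step_factor see [threshold_matrix()].
#' @return a `threshold_matrix`.
#' @export
read_threshold_matrix <- function(path, dilution_step_factor = 2) {
  df <- if (is.character(path)) utils::read.csv(path, stringsAsFactors = FALSE) else path
  need <- c("assessor_id", "round_index", "z_ite")
  if (length(setdiff(need, names(df))) > 0) {
    stop("threshold matrix table is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  assessors <- sort(unique(df$assessor_id))
  rounds <- sort(unique(df$round_index))
  m <- matrix(NA_real_, length(assessors), length(rounds),
              dimnames = list(assessors, rounds))
  m[cbind(match(df$assessor_id, assessors), match(df$round_index, rounds))] <- df$z_ite
  if (anyNA(m)) stop("incomplete threshold matrix: every assessor x round cell needs a z_ite")
  threshold_matrix(m, dilution_step_factor = dilution_step_factor)
}

#' Minimum number of individual threshold estimates for a valid measurement
#'
#' A valid odor-concentration measurement requires at least 12 individual
#' threshold estimates; with the minimum panel of 4 assessors this is reached
#' after 3 rounds (3 x 4 = 12).
#'
#' @param n_assessors,n_rounds panel geometry (defaults: the minimum panel).
#' @return integer: the Z_ITE count that panel produces.
#' @export
required_threshold_count <- function(n_assessors = 4, n_rounds = 3) {
  stopifnot(n_assessors >= 1, n_rounds >= 1)
  as.integer(n_assessors) * as.integer(n_rounds)
}

# Minimum Z_ITE count mandated for computing an odor concentration.
MIN_ZITE <- 12L

#' Odor concentration from a threshold matrix
#'
#' C_od (ou_E/m3) is the geometric mean of the individual threshold estimates
#' multiplied by the square root of the olfactometer's dilution step (default
#' step 2, multiplier sqrt(2)): the true threshold lies between the last
#' undetected and the first detected presentation, half a dilution step apart
#' on the log scale. At least 12 Z_ITE values are required.
#'
#' @param matrix a `threshold_matrix`.
#' @return positive scalar, ou_E/m3.
#' @examples
#' m <- threshold_matrix(rep(128, 12), n_assessors = 4, n_rounds = 3)
#' compute_odor_concentration(m) # 128 * sqrt(2)
#' @export
compute_odor_concentration <- function(matrix) {
  stopifnot(inherits(matrix, "threshold_matrix"))
  z <- as.numeric(matrix)
  if (length(z) < MIN_ZITE) {
    stop("at least ", MIN_ZITE, " individual threshold estimates (Z_ITE) are ",
         "required to compute an odor concentration; got ", length(z))
  }
  exp(mean(log(z))) * sqrt(attr(matrix, "dilution_step_factor"))
}

#' Retrospective screening of panel members
#'
#' After each measurement the panel is screened: for every individual
#' threshold estimate, the deviation delta_Z is the ratio of that Z_ITE to the
#' geometric mean of all Z_ITE in the matrix, and must satisfy
#' -delta_z_max <= delta_Z <= +delta_z_max (closed bounds; default 5). Since
#' dilution factors are positive the ratio is always positive and the lower
#' bound is vacuous; it is kept for fidelity to the screening rule as stated.
#'
#' @param matrix a `threshold_matrix`.
#' @param delta_z_max maximum admissible deviation (default 5).
#' @return an object of class `screening_result`: list with `delta_z` (matrix
#'   of ratios), `pass` (logical matrix), `overall_pass`, `delta_z_max`.
#' @export
screen_panel <- function(matrix, delta_z_max = 5) {
  stopifnot(inherits(matrix, "threshold_matrix"))
  if (!is.finite(delta_z_max) && !identical(delta_z_max, Inf)) {
    stop("delta_z_max must be positive (possibly Inf)")
  }
  if (delta_z_max <= 0) stop("delta_z_max must be positive")
  z <- unclass(matrix)
  gm <- exp(mean(log(z)))
  delta_z <- z / gm
  pass <- delta_z >= -delta_z_max & delta_z <= delta_z_max
  structure(
    list(delta_z = delta_z, pass = pass, overall_pass = all(pass),
         delta_z_max = delta_z_max),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Retrospective panel screening (|deltaZ| <=", x$delta_z_max, "):",
      if (x$overall_pass) "PASS" else "FAIL", "\n")
  if (!x$overall_pass) {
    bad <- which(!x$pass, arr.ind = TRUE)
    cat("  failing entries (assessor, round):",
        paste(apply(bad, 1, paste, collapse = ","), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Conservative safety multiplication factor k
#'
#' Two worst-case features of the olfactometric protocol compound: (i) the
#' screening rule tolerates an individual threshold up to `delta_z_max` times
#' the panel mean, so one panelist may perceive -- and therefore inhale -- at
#' a concentration `delta_z_max` times the panel-average threshold; (ii) every
#' perception must be confirmed at the next presentation, i.e. at twice the
#' perception concentration. The safety factor is their product,
#' k = delta_z_max x confirmation_factor = 5 x 2 = 10 by default.
#'
#' @param delta_z_max maximum admissible screening deviation (default 5).
#' @param confirmation_factor concentration ratio between the confirmation and
#'   perception presentations (default 2, the dilution step).
#' @return scalar k.
#' @examples
#' compute_safety_factor() # 10
#' @export
compute_safety_factor <- function(delta_z_max = 5, confirmation_factor = 2) {
  if (!is.finite(delta_z_max) || delta_z_max <= 0 ||
      !is.finite(confirmation_factor) || confirmation_factor <= 0) {
    stop("delta_z_max and confirmation_factor must be positive")
  }
  delta_z_max * confirmation_factor
}

#' Inhalation (exposure) concentration of a compound
#'
#' The concentration a panelist actually inhales at threshold is the sample
#' concentration diluted by the odor concentration; the safety factor k
#' covers between-assessor spread and the confirmation presentation:
#' Cin_i = (C_i / C_od) x k.
#'
#' @param c_i compound concentration in the undiluted sample, ug/m3 (>= 0).
#' @param c_od odor concentration of the sample, ou_E/m3 (> 0).
#' @param k safety multiplication factor (> 0), see [compute_safety_factor()].
#' @return inhalation concentration, ug/m3.
#' @examples
#' compute_inhalation_concentration(1000, 500, 10) # 20
#' @export
compute_inhalation_concentration <- function(c_i, c_od, k) {
  if (any(!is.finite(c_od)) || any(c_od <= 0)) {
    stop("c_od must be > 0: a sample without a valid odor concentration cannot be risk-assessed")
  }
  if (any(!is.finite(k)) || any(k <= 0)) stop("k must be > 0")
  if (any(c_i < 0)) stop("c_i must be >= 0")
  (c_i / c_od) * k
}
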