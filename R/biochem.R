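# Biochemical calculators: activities from absorbance slopes, purification
# tables, molar absorption coefficients, FAD occupancy and UV-Vis features.
# One unit (U) is the amount of enzyme oxidizing 1 umol of electron
# acceptor per minute.

#' Assay configuration
#'
#' Wavelength, extinction coefficient and cuvette path length for an
#' electron-acceptor assay. Presets cover the standard acceptors: DCIP at
#' 520 nm (6.9 mM^-1 cm^-1), DCIP at 600 nm for pH 8 (11.8) and cytochrome
#' c at 550 nm (19.6).
#'
#' @param acceptor Name, one of the presets (`"dcip520"`, `"dcip600"`,
#'   `"cytc550"`) or any label when `extinction` is supplied.
#' @param wavelength nm.
#' @param extinction mM^-1 cm^-1.
#' @param path Path length in cm.
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(acceptor = "dcip520", wavelength = NULL,
                         extinction = NULL, path = 1) {
  presets <- list(
    dcip520 = list(wavelength = 520, extinction = 6.9),
    dcip600 = list(wavelength = 600, extinction = 11.8),
    cytc550 = list(wavelength = 550, extinction = 19.6))
  if (is.null(extinction)) {
    if (!acceptor %in% names(presets)) {
      abort_param(sprintf("unknown acceptor '%s' and no extinction given",
                          acceptor))
    }
    wavelength <- presets[[acceptor]]$wavelength
    extinction <- presets[[acceptor]]$extinction
  }
  if (extinction <= 0 || wavelength <= 0 || path <= 0) {
    abort_param("extinction, wavelength and path must be positive")
  }
  structure(list(acceptor = acceptor, wavelength = wavelength,
                 extinction = extinction, path = path),
            class = "assay_config")
}

#' Volumetric activity from an absorbance trace
#'
#' Fits the absorbance-vs-time trace by ordinary least squares (over the
#' configured window, full trace by default) and converts the slope to a
#' volumetric activity: `slope / (extinction * path) * dilution /
#' sample_fraction`, in U mL^-1 (umol min^-1 per mL of enzyme sample),
#' since AU min^-1 over mM^-1 cm^-1 gives mM min^-1 = umol min^-1 mL^-1.
#' Negative fitted slopes clip to zero with a warning; a low R-squared
#' triggers a nonlinearity warning.
#'
#' @param trace Tibble with columns `time_min` and `absorbance` (at least
#'   3 points), or `NULL` when `slope` is given.
#' @param cfg An [assay_config()].
#' @param slope Precomputed slope in AU min^-1 (used when `trace` is NULL).
#' @param dilution Dilution factor of the enzyme sample (>= 1).
#' @param sample_fraction Sample volume as a fraction of reaction volume.
#' @param window Optional `c(from, to)` time window (min) for the fit.
#' @param r2_floor Minimum R-squared before a nonlinearity warning.
#' @return One-row tibble: `slope`, `r_squared`, `activity` (U mL^-1).
#' @export
volumetric_activity <- function(trace = NULL, cfg = assay_config(),
                                slope = NULL, dilution = 1,
                                sample_fraction = 1, window = NULL,
                                r2_floor = 0.9) {
  stopifnot(inherits(cfg, "assay_config"))
  if (dilution < 1) abort_param("dilution must be >= 1")
  r2 <- NA_real_
  if (is.null(slope)) {
    if (is.null(trace) || nrow(trace) < 3) {
      abort_param("need a trace with >= 3 points or a precomputed slope")
    }
    if (any(diff(trace$time_min) <= 0)) {
      abort_param("trace time must be strictly increasing")
    }
    if (!is.null(window)) {
      trace <- trace[trace$time_min >= window[1] & trace$time_min <= window[2], ]
    }
    fit <- stats::lm(absorbance ~ time_min, data = trace)
    slope <- unname(stats::coef(fit)[2])
    # suppressed: summary.lm warns on noiseless (perfect-fit) traces
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (!is.na(r2) && r2 < r2_floor && abs(slope) > .Machine$double.eps) {
      warning(sprintf("linear fit R^2 = %.3f below %.2f: trace may be nonlinear",
                      r2, r2_floor), call. = FALSE)
    }
  }
  if (slope < 0) {
    warning("negative fitted slope clipped to 0", call. = FALSE)
    slope <- 0
  }
  activity <- slope / (cfg$extinction * cfg$path) * dilution / sample_fraction
  tibble::tibble(slope = slope, r_squared = r2, activity = activity)
}

#' Limit of quantification from blank reactions
#'
#' Ten times the sample standard deviation (n-1 denominator) of blank
#' measurements.
#'
#' @param blanks Numeric vector of blank activities (>= 3 values).
#' @return The quantification threshold, same units as `blanks`.
#' @export
limit_of_quantification <- function(blanks) {
  if (length(blanks) < 3) abort_param("need at least 3 blank measurements")
  10 * stats::sd(blanks)
}

parse_activity <- function(x) {
  if (is.numeric(x)) return(list(value = x, bdl = rep(FALSE, length(x))))
  xx <- trimws(as.character(x))
  bdl <- grepl("^b\\.?d\\.?l\\.?$", xx, ignore.case = TRUE)
  val <- suppressWarnings(as.numeric(xx))
  val[bdl] <- NA_real_
  list(value = val, bdl = bdl)
}

#' Compute a purification table
#'
#' Derives, per step and per assay, the standard purification-table
#' columns: total protein (`conc * volume` unless `total_protein` is given
#' explicitly), specific activity (total activity / total protein), yield
#' (percent of the reference step's total activity), purification factor
#' (specific activity over the reference step's) and RZ (`A420 / A280`).
#' The first step (the supernatant) is the reference. Activities below the
#' detection limit are entered as the string `"b.d.l."` and propagate as a
#' distinct state (`bdl = TRUE`, derived values NA), never as zero. All
#' computation is at full precision; rounding is for display only.
#'
#' @param steps Tibble, one row per step: `step`, `volume` (mL), `conc`
#'   (mg mL^-1) and/or `total_protein` (mg), one or more activity columns
#'   named `total_activity_<assay>` (numeric or character with `"b.d.l."`),
#'   optional `a420`, `a280`.
#' @param reference Row index of the reference step (default 1).
#' @return A tibble in long form: `step`, `assay`, `volume`,
#'   `total_protein`, `total_activity`, `bdl`, `specific_activity`,
#'   `yield_pct`, `purification_factor`, `rz`.
#' @export
purification_table <- function(steps, reference = 1) {
  stopifnot(is.data.frame(steps), nrow(steps) >= 1, "step" %in% names(steps))
  act_cols <- grep("^total_activity_", names(steps), value = TRUE)
  if (length(act_cols) == 0) abort_param("no total_activity_<assay> columns")
  total_protein <- if ("total_protein" %in% names(steps) &&
                       any(!is.na(steps$total_protein))) {
    ifelse(!is.na(steps$total_protein), steps$total_protein,
           steps$conc * steps$volume)
  } else {
    steps$conc * steps$volume
  }
  if (any(total_protein < 0, na.rm = TRUE)) abort_param("negative protein amounts")
  rz <- if (all(c("a420", "a280") %in% names(steps))) {
    steps$a420 / steps$a280
  } else rep(NA_real_, nrow(steps))

  out <- purrr::map_dfr(act_cols, function(col) {
    assay <- sub("^total_activity_", "", col)
    parsed <- parse_activity(steps[[col]])
    ref_act <- parsed$value[reference]
    if (is.na(ref_act) || parsed$bdl[reference] || ref_act == 0) {
      abort_param(sprintf("reference step has zero/undetectable %s activity",
                          assay))
    }
    spec <- parsed$value / total_protein
    tibble::tibble(
      step = steps$step,
      assay = assay,
      volume = if ("volume" %in% names(steps)) steps$volume else NA_real_,
      total_protein = total_protein,
      total_activity = parsed$value,
      bdl = parsed$bdl,
      specific_activity = spec,
      yield_pct = 100 * parsed$value / ref_act,
      purification_factor = spec / spec[reference],
      rz = rz)
  })
  out
}

#' Molar absorption coefficient at 280 nm from sequence
#'
#' `epsilon280 = 5500 nTrp + 1490 nTyr + 125 nCystine` (M^-1 cm^-1), where
#' the cystine count assumes all cysteines pairwise disulfide-bonded
#' (`floor(nCys / 2)`); set `cysteines = "reduced"` for no cystine
#' contribution.
#'
#' @param sequence Protein sequence string (mature chain).
#' @param cysteines `"paired"` (default) or `"reduced"`.
#' @return epsilon280 in M^-1 cm^-1.
#' @export
epsilon280_from_sequence <- function(sequence, cysteines = c("paired", "reduced")) {
  cysteines <- match.arg(cysteines)
  s <- toupper(sequence)
  if (nchar(s) == 0) abort_param("empty sequence")
  ch <- seq_chars(s)
  n_trp <- sum(ch == "W"); n_tyr <- sum(ch == "Y"); n_cys <- sum(ch == "C")
  n_cystine <- if (cysteines == "paired") n_cys %/% 2 else 0
  5500 * n_trp + 1490 * n_tyr + 125 * n_cystine
}

#' Protein concentration from A280
#'
#' @param a280 Absorbance at 280 nm (AU).
#' @param epsilon280 M^-1 cm^-1.
#' @param molar_mass g mol^-1 (optional; enables the mass concentration).
#' @param path Path length (cm).
#' @return One-row tibble: `molar` (mol L^-1) and `mass_g_per_l` (NA
#'   without `molar_mass`).
#' @export
protein_conc <- function(a280, epsilon280, molar_mass = NULL, path = 1) {
  if (a280 < 0 || epsilon280 <= 0 || path <= 0) abort_param("inputs must be positive")
  molar <- a280 / (epsilon280 * path)
  tibble::tibble(molar = molar,
                 mass_g_per_l = if (is.null(molar_mass)) NA_real_ else
                   molar * molar_mass)
}

#' FAD occupancy from TCA-released flavin absorbance
#'
#' The flavin concentration comes from the A450 of the TCA supernatant;
#' the protein concentration estimate starts from the native A280 and is
#' iteratively corrected for the flavin's own 280 nm contribution until the
#' fixed point: `P_{k+1} = (A280 - FAD * eps_fad280) / eps_prot280`. With
#' the default `eps_fad280 = 0` the non-iterative estimate is returned.
#' Occupancy is FAD / protein, clipped to \[0, 1.05\] with a warning above 1.
#'
#' @param a450 Absorbance of the released flavin at 450 nm (AU).
#' @param a280 Native protein absorbance at 280 nm (AU).
#' @param eps_prot280 Protein molar absorption coefficient (M^-1 cm^-1).
#' @param eps_fad450 Flavin coefficient at 450 nm (M^-1 cm^-1; default
#'   11300, i.e. 11.3 mM^-1 cm^-1).
#' @param eps_fad280 Flavin coefficient at 280 nm (M^-1 cm^-1; default 0).
#' @param path Path length (cm).
#' @param tol Fixed-point convergence tolerance (M).
#' @param max_iter Iteration cap.
#' @return One-row tibble: `fad_molar`, `protein_molar`, `occupancy`.
#' @export
fad_occupancy <- function(a450, a280, eps_prot280, eps_fad450 = 11300,
                          eps_fad280 = 0, path = 1, tol = 1e-9,
                          max_iter = 100) {
  if (a450 < 0 || a280 <= 0) abort_param("absorbances must be positive")
  fad <- a450 / (eps_fad450 * path)
  p <- a280 / (eps_prot280 * path)
  for (i in seq_len(max_iter)) {
    corrected <- a280 - fad * eps_fad280 * path
    if (corrected <= 0) abort_param("flavin correction exceeds the native A280")
    p_new <- corrected / (eps_prot280 * path)
    if (abs(p_new - p) < tol) { p <- p_new; break }
    p <- p_new
    if (i == max_iter) abort_param("FAD occupancy iteration did not converge")
  }
  occ <- fad / p
  if (occ > 1) {
    warning(sprintf("occupancy %.3f above 1 clipped to at most 1.05", occ),
            call. = FALSE)
  }
  occ <- min(max(occ, 0), 1.05)
  tibble::tibble(fad_molar = fad, protein_molar = p, occupancy = occ)
}

#' Normalize a specific activity to 100% FAD loading
#'
#' Divides the measured specific activity by the flavin occupancy,
#' reporting the activity the preparation would show at full cofactor
#' loading. Monotone decreasing in occupancy; the identity at occupancy 1.
#' When uncertainties are supplied, relative errors add in quadrature.
#'
#' @param specific_activity U mg^-1.
#' @param occupancy Fraction in (0, 1].
#' @param activity_sd,occupancy_sd Optional symmetric uncertainties.
#' @return One-row tibble: `specific_activity_full_fad`, `sd` (NA without
#'   uncertainties).
#' @export
normalize_to_full_fad <- function(specific_activity, occupancy,
                                  activity_sd = NULL, occupancy_sd = NULL) {
  if (any(occupancy <= 0)) abort_param("occupancy must be positive")
  if (any(occupancy > 1)) abort_param("occupancy must be at most 1")
  value <- specific_activity / occupancy
  sd_out <- if (!is.null(activity_sd) || !is.null(occupancy_sd)) {
    ra <- if (is.null(activity_sd)) 0 else activity_sd / specific_activity
    ro <- if (is.null(occupancy_sd)) 0 else occupancy_sd / occupancy
    value * sqrt(ra^2 + ro^2)
  } else NA_real_
  tibble::tibble(specific_activity_full_fad = value, sd = sd_out)
}

interp_at <- function(spectrum, wl) {
  stats::approx(spectrum$wavelength, spectrum$absorbance, xout = wl)$y
}

# quadratic interpolation of a peak apex around the grid maximum inside a
# window; returns NA position when no interior local maximum exists
find_peak <- function(spectrum, lo, hi) {
  idx <- which(spectrum$wavelength >= lo & spectrum$wavelength <= hi)
  if (length(idx) < 3) return(list(position = NA_real_, height = NA_real_))
  a <- spectrum$absorbance[idx]
  w <- spectrum$wavelength[idx]
  k <- which.max(a)
  if (k == 1 || k == length(idx)) return(list(position = NA_real_, height = NA_real_))
  if (a[k] <= a[k - 1] || a[k] <= a[k + 1]) {
    return(list(position = NA_real_, height = NA_real_))
  }
  # parabola through the three points around the apex
  x <- w[(k - 1):(k + 1)] - w[k]
  y <- a[(k - 1):(k + 1)]
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  A <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
  B <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
  if (A >= 0) return(list(position = w[k], height = a[k]))
  xv <- -B / (2 * A)
  list(position = w[k] + xv, height = y[2] - B^2 / (4 * A))
}

#' Spectral features of oxidized/reduced UV-Vis spectra
#'
#' Detects the heme b Soret maximum in the 400-440 nm window for each
#' state (quadratic interpolation around the grid maximum; a spectrum with
#' no interior local maximum there — e.g. an isolated DH domain without
#' heme — is flagged `no Soret band`), reports the oxidized-to-reduced
#' peak shift, the RZ purity ratio (`A420 / A280` of the oxidized
#' spectrum), the alpha/beta band amplitudes (545-575 and 515-545 nm) and
#' the reduced-minus-oxidized difference spectrum on the common grid.
#'
#' @param ox Oxidized spectrum: tibble `wavelength` (nm, increasing),
#'   `absorbance` (AU), covering at least 260-600 nm.
#' @param red Optional reduced spectrum on a compatible grid.
#' @return A `cdh_spectral_features` list: `soret` (tibble `state`,
#'   `peak_nm`, `height`, `no_soret`), `shift_nm`, `rz`, `bands`,
#'   `difference` (tibble, NULL without `red`).
#' @export
spectral_features <- function(ox, red = NULL) {
  check_spectrum <- function(sp, what) {
    stopifnot(all(c("wavelength", "absorbance") %in% names(sp)))
    if (any(diff(sp$wavelength) <= 0)) abort_param(sprintf("%s grid not increasing", what))
    if (min(sp$wavelength) > 260 || max(sp$wavelength) < 600) {
      abort_param(sprintf("%s spectrum must cover 260-600 nm", what))
    }
  }
  check_spectrum(ox, "oxidized")
  states <- list(oxidized = ox)
  if (!is.null(red)) { check_spectrum(red, "reduced"); states$reduced <- red }

  soret <- purrr::map_dfr(names(states), function(st) {
    pk <- find_peak(states[[st]], 400, 440)
    tibble::tibble(state = st, peak_nm = pk$position, height = pk$height,
                   no_soret = is.na(pk$position))
  })
  shift <- if (nrow(soret) == 2 && !any(soret$no_soret)) {
    soret$peak_nm[soret$state == "reduced"] -
      soret$peak_nm[soret$state == "oxidized"]
  } else NA_real_
  rz <- interp_at(ox, 420) / interp_at(ox, 280)
  bands <- purrr::map_dfr(names(states), function(st) {
    tibble::tibble(state = st,
                   alpha = find_peak(states[[st]], 545, 575)$height,
                   beta = find_peak(states[[st]], 515, 545)$height)
  })
  difference <- NULL
  if (!is.null(red)) {
    grid <- ox$wavelength[ox$wavelength >= max(min(red$wavelength), min(ox$wavelength)) &
                            ox$wavelength <= min(max(red$wavelength), max(ox$wavelength))]
    difference <- tibble::tibble(
      wavelength = grid,
      absorbance = stats::approx(red$wavelength, red$absorbance, xout = grid)$y -
        stats::approx(ox$wavelength, ox$absorbance, xout = grid)$y)
  }
  structure(list(soret = soret, shift_nm = shift, rz = rz, bands = bands,
                 difference = difference),
            class = "cdh_spectral_features")
}

#' @export
print.cdh_spectral_features <- function(x, ...) {
  print(x$soret)
  cat(sprintf("Soret shift: %s nm; RZ (A420/A280, oxidized): %.3f\n",
              format(x$shift_nm), x$rz))
  invisible(x)
}
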