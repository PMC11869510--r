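#' Sample latent tumor histories
#'
#' At most one first primary per woman. Onset ages follow the configured
#' age-specific piecewise-constant hazard (times `hr_high` for high-risk women)
#' by inverse transform; women whose quantile exceeds the cumulative hazard at
#' age 120 never develop disease. A fraction of onsets start as DCIS; a configurable
#' share of those progress to invasive disease after an exponential dwell.
#' Diameter grows exponentially from `d0_mm` with a lognormal per-woman rate.
#' Nodal and metastatic transitions are size-triggered: each tumor draws
#' lognormal diameter thresholds (the metastasis threshold floored at the nodal
#' one, so spread is ordered), crossed when the growth curve reaches them and
#' only while the history is invasive; thresholds above the growth cap are
#' never reached. Symptomatic surfacing has hazard proportional to diameter,
#' so every history surfaces clinically in finite time.
#'
#' @param pop Population table from [generate_population()].
#' @param nh Natural-history parameters, see [default_nh_params()].
#' @return `data.table`, one row per woman with disease: id, onset_age, kind0
#'   (`"DCIS"`/`"invasive"`), progression_age (`Inf` if a DCIS never
#'   progresses, `NA` for invasive onsets), growth_rate (per-year log-diameter),
#'   node_age, met_age (`Inf` if never), surfacing_age, sojourn_years.
#' @export
sample_tumor_history <- function(pop, nh = default_nh_params()) {
  validate_nh_params(nh)
  n <- nrow(pop)
  hr <- ifelse(pop$risk_class == "high", nh$hr_high, 1)

  # piecewise-constant hazard: invert the piecewise-linear cumulative hazard
  rate <- nh$onset_hazard$rate
  H <- c(0, cumsum(rate))               # cumulative hazard at exact ages 0..120
  u <- runif(n)
  target <- -log(1 - u) / hr
  has <- target < H[length(H)]
  tgt <- target[has]
  idx <- findInterval(tgt, H, left.open = TRUE)  # onset during year of age idx-1
  onset_age <- (idx - 1) + (tgt - H[idx]) / rate[idx]

  h <- data.table(id = pop$id[has], onset_age = onset_age)
  m <- nrow(h)
  h[, kind0 := ifelse(runif(m) < nh$dcis_fraction, "DCIS", "invasive")]
  h[, growth_rate := rlnorm(m, nh$growth_meanlog, nh$growth_sdlog)]

  # DCIS -> invasive progression after an exponential dwell (or never)
  h[, progression_age := NA_real_]
  h[kind0 == "DCIS",
    progression_age := onset_age +
      ifelse(runif(.N) < nh$dcis_progression_prob,
             rexp(.N, 1 / nh$dcis_dwell_mean), Inf)]

  # invasive clock: time since onset from which spread may occur
  inv_start <- fifelse(h$kind0 == "DCIS", h$progression_age - h$onset_age, 0)

  r <- h$growth_rate
  d_node <- rlnorm(m, nh$node_size_meanlog, nh$node_size_sdlog)
  d_met <- pmax(d_node, rlnorm(m, nh$met_size_meanlog, nh$met_size_sdlog))
  # time (since onset) at which the growth curve crosses a threshold; the cap
  # makes thresholds beyond it unreachable
  cross <- function(d_thr) {
    t <- log(d_thr / nh$d0_mm) / r
    fifelse(d_thr <= nh$size_cap_mm, pmax(t, inv_start), Inf)
  }
  h[, node_age := onset_age + cross(d_node)]
  h[, met_age := onset_age + pmax(cross(d_met), cross(d_node))]

  # clinical surfacing: hazard b * d(t) => closed-form inverse
  b <- nh$surfacing_hazard_per_mm
  h[, surfacing_age := onset_age + log(1 + growth_rate * rexp(m) / (b * nh$d0_mm)) / growth_rate]
  h[, sojourn_years := surfacing_age - onset_age]
  setkey(h, id)
  h[]
}

#' Tumor diameter at a given age
#'
#' @param history Rows of a [sample_tumor_history()] table (recycled columns
#'   `onset_age`, `growth_rate`).
#' @param age Ages at which to evaluate (same length or scalar).
#' @param nh Natural-history parameters (for `d0_mm`, `size_cap_mm`).
#' @return Diameters in mm; `NA` before onset.
#' @export
tumor_size_at <- function(history, age, nh = default_nh_params()) {
  dt <- age - history$onset_age
  size <- pmin(nh$size_cap_mm, nh$d0_mm * exp(history$growth_rate * dt))
  fifelse(dt >= 0, size, NA_real_)
}

#' Disease state (kind, size, N, M) at a given age
#'
#' @inheritParams tumor_size_at
#' @return `data.table(kind, size_mm, node_positive, metastasis)`.
#' @export
tumor_state_at <- function(history, age, nh = default_nh_params()) {
  prog <- fifelse(is.na(history$progression_age), -Inf, history$progression_age)
  data.table(
    kind = fifelse(history$kind0 == "DCIS" & age < prog, "DCIS", "invasive"),
    size_mm = tumor_size_at(history, age, nh),
    node_positive = age >= history$node_age,
    metastasis = age >= history$met_age
  )
}

# cache for the TNM lookup shipped with the package
.mammosim_env <- new.env(parent = emptyenv())

#' The packaged TNM-to-stage lookup
#'
#' Simplified stage grouping from tumor size (T1 < 20 mm, T2 20--50 mm,
#' T3 > 50 mm), nodal status (N0/N1) and metastasis (M0/M1); shipped as a
#' versioned CSV (`inst/extdata/tnm_stage_map.csv`).
#'
#' @return `data.frame` of the mapping.
#' @export
tnm_stage_map <- function() {
  if (is.null(.mammosim_env$tnm)) {
    .mammosim_env$tnm <- read.csv(
      system.file("extdata", "tnm_stage_map.csv", package = "mammosim"),
      colClasses = c("character", "character", "character", "character", "character"))
  }
  .mammosim_env$tnm
}

#' Classify stage from kind, size, nodal status and metastasis
#'
#' Deterministic and monotone: enlarging the tumor or adding spread never
#' lowers the stage. DCIS at diagnosis is stage 0; M1 is stage IV regardless of
#' T and N.
#'
#' @param kind `"DCIS"` or `"invasive"` (vectorized).
#' @param size_mm Tumor diameter in mm (> 0).
#' @param node_positive,metastasis Logicals.
#' @return Character vector with levels `"0", "I", "II", "III", "IV"`.
#' @export
#' @examples
#' classify_stage("DCIS", 5, FALSE, FALSE)      # "0"
#' classify_stage("invasive", 15, TRUE, FALSE)  # "II"
classify_stage <- function(kind, size_mm, node_positive, metastasis) {
  stopifnot(all(size_mm > 0, na.rm = TRUE))
  n <- max(length(kind), length(size_mm), length(node_positive), length(metastasis))
  kind <- rep_len(kind, n); size_mm <- rep_len(size_mm, n)
  node_positive <- rep_len(node_positive, n); metastasis <- rep_len(metastasis, n)

  t_cat <- ifelse(size_mm < 20, "T1", ifelse(size_mm <= 50, "T2", "T3"))
  map <- tnm_stage_map()
  out <- rep(NA_character_, n)
  out[metastasis] <- map$stage[map$metastasis == "TRUE"][1]
  dcis <- !metastasis & kind == "DCIS"
  out[dcis] <- "0"
  inv <- !metastasis & !dcis
  if (any(inv)) {
    sub <- map[map$kind == "invasive" & map$metastasis == "FALSE", ]
    key <- paste(t_cat[inv], node_positive[inv])
    lut <- setNames(sub$stage, paste(sub$t_cat, sub$node_positive == "TRUE"))
    out[inv] <- lut[key]
  }
  out
}

#' Stage at a given age for a set of histories
#'
#' @inheritParams tumor_size_at
#' @return Character stage vector.
#' @export
stage_at <- function(history, age, nh = default_nh_params()) {
  st <- tumor_state_at(history, age, nh)
  classify_stage(st$kind, st$size_mm, st$node_positive, st$metastasis)
}

#' Theoretical mean sojourn time under the configured surfacing hazard
#'
#' Independent oracle for parameter recovery: integrates the closed-form
#' conditional mean `E[T | r] = E_E[log(1 + r E / (b d0)) / r]` over the
#' lognormal growth-rate distribution by Gauss-style quadrature on quantiles.
#'
#' @param nh Natural-history parameters.
#' @param n_quad Number of quantile nodes for the growth-rate average.
#' @return Mean onset-to-surfacing time in years.
#' @export
theoretical_mean_sojourn <- function(nh = default_nh_params(), n_quad = 512) {
  b <- nh$surfacing_hazard_per_mm * nh$d0_mm
  mean_given_r <- function(r) {
    vapply(r, function(ri) {
      integrate(function(e) log(1 + ri * e / b) * exp(-e), 0, Inf,
                rel.tol = 1e-9)$value / ri
    }, numeric(1))
  }
  q <- qlnorm((seq_len(n_quad) - 0.5) / n_quad, nh$growth_meanlog, nh$growth_sdlog)
  mean(mean_given_r(q))
}
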