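#' PERT distribution parameters and sampling
#'
#' The PERT distribution is the scaled Beta with shape parameters
#' `alpha1 = 1 + 4 (b - a) / (c - a)`, `alpha2 = 1 + 4 (c - b) / (c - a)`
#' (shape constant 4), minimum `a`, most-likely `b`, maximum `c`, and
#' mean `(a + 4 b + c) / 6`. `pert_sample()` maps uniforms through the
#' inverse regularized incomplete Beta function, so stratified uniforms
#' yield stratified PERT draws. A degenerate triple `a = b = c` is a
#' point mass.
#'
#' @param a,b,c minimum, most-likely and maximum (same units),
#'   `a <= b <= c`.
#' @return `pert_params()` returns an object of class `pert_params`.
#' @export
pert_params <- function(a, b, c) {
  if (!(a <= b && b <= c))
    stop("PERT parameters require a <= b <= c (got ", a, ", ", b, ", ", c,
         ")", call. = FALSE)
  structure(list(a = a, b = b, c = c), class = "pert_params")
}

#' @export
print.pert_params <- function(x, ...) {
  cat(sprintf("Pert(%g, %g, %g), mean %g\n", x$a, x$b, x$c, pert_mean(x)))
  invisible(x)
}

#' @rdname pert_params
#' @param params a `pert_params` object.
#' @param u uniforms in (0, 1).
#' @export
pert_sample <- function(params, u) {
  stopifnot(inherits(params, "pert_params"), all(u > 0 & u < 1))
  with(params, {
    if (a == c) return(rep(a, length(u)))
    alpha1 <- 1 + 4 * (b - a) / (c - a)
    alpha2 <- 1 + 4 * (c - b) / (c - a)
    a + (c - a) * stats::qbeta(u, alpha1, alpha2)
  })
}

#' @rdname pert_params
#' @export
pert_mean <- function(params) {
  with(params, (a + 4 * b + c) / 6)
}

#' Latin hypercube sample
#'
#' `n x k` uniforms with exact stratification: per column, exactly one
#' draw falls in each of the `n` equal-probability strata
#' `((i-1)/n, i/n)`, uniform within its stratum, with stratum order
#' permuted independently per column. Deterministic given the seed.
#'
#' @param n rows (samples); `k` columns (variables).
#' @param k number of columns.
#' @param seed integer seed.
#' @return An `n x k` matrix of uniforms in (0, 1).
#' @export
lhs_sample <- function(n, k, seed = 1) {
  stopifnot(n >= 1, k >= 1)
  set.seed(as.integer(seed))
  lhs::randomLHS(n, k)
}

#' Economic risk scenario configuration
#'
#' Bundles the PERT parameters of the stochastic inputs of the
#' loss/benefit model, the benefit-correction constant `D`, the
#' iteration count and the seed. `default_scenario_config()` returns
#' the packaged rice-pest parameterization for China (yields and areas
#' from national production statistics; damage, loss and control rates
#' from field literature), with percent-valued inputs already converted
#' to fractions and the unit prevention cost `C` interpreted as $ per
#' hm^2 (the only unit under which `F2 = S * I * C` is a dollar
#' amount).
#'
#' Inputs: `Q` rice yield in suitable habitats (t), `I` damage rate
#' (fraction), `R` yield loss rate (fraction), `Pa` market price ($/t),
#' `S` planted area in suitable habitats (hm^2), `C` unit prevention
#' cost ($/hm^2), `W` unit yield (t/hm^2), `M` control effect
#' (fraction).
#'
#' @param Q,I,R,Pa,S,C,W,M `pert_params` for the stochastic inputs.
#' @param D benefit-correction constant (> 0).
#' @param n_iterations Monte-Carlo iterations (>= 1000).
#' @param seed integer seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(Q, I, R, Pa, S, C, W, M, D = 2,
                            n_iterations = 100000, seed = 1) {
  inputs <- list(Q = Q, I = I, R = R, Pa = Pa, S = S, C = C, W = W, M = M)
  ok <- vapply(inputs, inherits, logical(1), "pert_params")
  if (!all(ok))
    stop("inputs must be pert_params: ", paste(names(inputs)[!ok],
         collapse = ", "), call. = FALSE)
  for (nm in c("I", "R", "M"))
    if (inputs[[nm]]$a < 0 || inputs[[nm]]$c > 1)
      stop(nm, " must be a fraction within [0, 1]; convert percents first",
           call. = FALSE)
  stopifnot(D > 0, n_iterations >= 1000)
  structure(c(inputs, list(D = D, n_iterations = as.integer(n_iterations),
                           seed = as.integer(seed))),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @export
default_scenario_config <- function(n_iterations = 100000, seed = 1) {
  scenario_config(
    Q = pert_params(192633999.68, 194501221, 196083353.35),
    I = pert_params(0.10, 0.30, 0.50),
    R = pert_params(0.159, 0.5135, 0.868),
    Pa = pert_params(374.12, 402.32, 544.83),
    S = pert_params(27363597.06, 27683966.83, 27966379.44),
    C = pert_params(5.87, 39.85, 110.64),
    W = pert_params(6.99, 7.03, 7.07),
    M = pert_params(0.7244, 0.7835, 0.8425),
    D = 2, n_iterations = n_iterations, seed = seed)
}

#' Read a scenario configuration from YAML or JSON
#'
#' The file holds one entry per input with `min`, `mode`, `max` and an
#' optional `percent: true` flag (values divided by 100 at load), plus
#' `D`, `n_iterations`, `seed`. The packaged default lives at
#' `system.file("extdata", "scenario_rice_china.yaml", package =
#' "pestrisk")`.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  get_pert <- function(nm) {
    e <- cfg$inputs[[nm]]
    if (is.null(e)) stop("config is missing input '", nm, "'", call. = FALSE)
    div <- if (isTRUE(e$percent)) 100 else 1
    pert_params(e$min / div, e$mode / div, e$max / div)
  }
  inputs <- lapply(stats::setNames(nm = c("Q", "I", "R", "Pa", "S", "C",
                                          "W", "M")), get_pert)
  do.call(scenario_config, c(inputs, list(
    D = cfg$D %||% 2,
    n_iterations = cfg$n_iterations %||% 100000,
    seed = cfg$seed %||% 1)))
}

#' Run the stochastic loss/benefit simulation
#'
#' Draws one Latin-hypercube column per stochastic input (all mutually
#' independent), shares the draws across all quantities within an
#' iteration, and evaluates elementwise:
#' \describe{
#'   \item{E}{`C * D / (W * Pa * M)` — the economic loss level after
#'     control, a dimensionless fraction;}
#'   \item{F1}{`Q * I * R * Pa / (1 - I * R)` — loss without control;}
#'   \item{F2}{`S * I * C` — management cost;}
#'   \item{F3}{`Q * I * E * Pa / (1 - I * E)` — residual loss under
#'     control;}
#'   \item{F4}{`F2 + F3` — total cost under control;}
#'   \item{F5}{`F1 - F4` — potential savings from control.}
#' }
#' The identities `F4 = F2 + F3` and `F5 = F1 - F4` hold exactly by
#' construction. A draw with `1 - I*R <= 0` or `1 - I*E <= 0` is a
#' hard error naming the offending parameterization.
#'
#' @param config a [scenario_config()].
#' @return An object of class `risk_result`: `samples` (tibble with the
#'   eight inputs, `E`, and `F1`-`F5` per iteration), `summary` (via
#'   [summarize_risk()]), `sensitivity` (per-output Spearman tables via
#'   [sensitivity_spearman()]), `config`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  input_names <- c("Q", "I", "R", "Pa", "S", "C", "W", "M")
  U <- lhs_sample(config$n_iterations, length(input_names),
                  seed = config$seed)
  draws <- purrr::imap(stats::setNames(nm = input_names),
                       function(nm, i) pert_sample(config[[nm]], U[, match(nm, input_names)]))
  s <- tibble::as_tibble(draws)
  E <- s$C * config$D / (s$W * s$Pa * s$M)
  if (any(1 - s$I * s$R <= 0))
    stop("1 - I*R <= 0 for some draws: max(I)*max(R) must stay below 1",
         call. = FALSE)
  if (any(1 - s$I * E <= 0))
    stop("1 - I*E <= 0 for some draws: control-level parameterization invalid",
         call. = FALSE)
  s$E <- E
  s$F1 <- s$Q * s$I * s$R * s$Pa / (1 - s$I * s$R)
  s$F2 <- s$S * s$I * s$C
  s$F3 <- s$Q * s$I * s$E * s$Pa / (1 - s$I * s$E)
  s$F4 <- s$F2 + s$F3
  s$F5 <- s$F1 - s$F4
  outputs <- c("E", "F1", "F2", "F3", "F4", "F5")
  sens <- purrr::map(stats::setNames(nm = c("F1", "F2", "F3", "F4", "F5")),
                     function(o) sensitivity_spearman(s[input_names], s[[o]]))
  structure(list(samples = s,
                 summary = summarize_risk(s[outputs]),
                 sensitivity = sens, config = config),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("<risk_result> %d iterations, seed %d\n",
              x$config$n_iterations, x$config$seed))
  sm <- dplyr::filter(x$summary, .data$quantity != "E")
  cat("  95% intervals (billion USD):\n")
  for (i in seq_len(nrow(sm)))
    cat(sprintf("    %s: [%.2f, %.2f], midpoint %.2f, mean %.2f\n",
                sm$quantity[i], sm$q2.5_bn[i], sm$q97.5_bn[i],
                sm$mid95_bn[i], sm$mean_bn[i]))
  invisible(x)
}

#' Summary statistics of simulated quantities
#'
#' Mean, standard deviation, median and the 2.5/5/95/97.5 percentiles
#' (linear-interpolation quantiles) per quantity, in native units and
#' rescaled (default billions, rounded to 2 decimals). The midpoint of
#' the equal-tailed 95% interval is reported alongside the sample mean
#' because risk-software summaries often print the former.
#'
#' @param samples data frame (columns = quantities) or numeric vector.
#' @param unit_scale divisor for the rescaled columns (default 1e9).
#' @return A tibble with one row per quantity: `mean`, `sd`, `median`,
#'   `q2.5`, `q5`, `q95`, `q97.5`, `mid95`, and `_bn`-suffixed rescaled
#'   versions.
#' @export
summarize_risk <- function(samples, unit_scale = 1e9) {
  if (is.numeric(samples)) samples <- tibble::tibble(value = samples)
  stopifnot(nrow(samples) >= 1000)
  purrr::imap_dfr(samples, function(x, nm) {
    qs <- stats::quantile(x, c(0.025, 0.05, 0.95, 0.975), names = FALSE)
    tibble::tibble(
      quantity = nm, mean = mean(x), sd = stats::sd(x),
      median = stats::median(x),
      q2.5 = qs[1], q5 = qs[2], q95 = qs[3], q97.5 = qs[4],
      mid95 = (qs[1] + qs[4]) / 2,
      mean_bn = round(mean(x) / unit_scale, 2),
      q2.5_bn = round(qs[1] / unit_scale, 2),
      q97.5_bn = round(qs[4] / unit_scale, 2),
      mid95_bn = round((qs[1] + qs[4]) / 2 / unit_scale, 2))
  })
}

#' Spearman rank sensitivity of an output to its inputs
#'
#' Rank correlation of each input column with the output, sorted by
#' absolute value — the ordering behind a tornado chart. A constant
#' input has undefined correlation and is reported as 0 with a flag.
#'
#' @param input_samples data frame of input draws.
#' @param output_samples numeric output vector of the same length.
#' @return A tibble with `variable`, `rho`, `rank`, `constant`.
#' @export
sensitivity_spearman <- function(input_samples, output_samples) {
  input_samples <- tibble::as_tibble(input_samples)
  stopifnot(nrow(input_samples) == length(output_samples),
            nrow(input_samples) >= 3)
  rho <- purrr::imap_dfr(input_samples, function(x, nm) {
    const <- stats::sd(x) == 0 || stats::sd(output_samples) == 0
    tibble::tibble(
      variable = nm,
      rho = if (const) 0 else
        stats::cor(x, output_samples, method = "spearman"),
      constant = const)
  })
  rho <- dplyr::arrange(rho, dplyr::desc(abs(.data$rho)))
  dplyr::mutate(rho, rank = dplyr::row_number(), .after = "rho")
}
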