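#' Built-in worked-example scenarios
#'
#' Three ready-made four-program reallocation scenarios used throughout the
#' documentation and tests:
#' \describe{
#'   \item{`"deterministic"`}{Known costs/effects. A: 100,000 kUSD / 150 LY;
#'     a: 40,000 / 90; B: 140,000 / 50; b: 70,000 / 30. The rule verdict is
#'     efficient with net outcome (−10,000 kUSD, +40 LY).}
#'   \item{`"variance_decreasing"`}{Same means; the newly funded portfolio
#'     \{A, b\} has SDs of 5000 kUSD / 5 LY against 13,000 / 13 for the
#'     displaced portfolio \{a, B\} — the reallocation reduces portfolio
#'     risk. Within-program cost–effect correlation 0.5 everywhere.}
#'   \item{`"variance_increasing"`}{The mirror image: \{A, b\} carry the
#'     13,000 / 13 SDs and \{a, B\} the 5000 / 5 — portfolio risk grows.
#'     The net-outcome distribution on the plane is identical to the
#'     variance-decreasing case because net variances sum over all four
#'     programs.}
#' }
#'
#' @param which One of `"deterministic"`, `"variance_decreasing"`,
#'   `"variance_increasing"`.
#' @param rho Within-program cost–effect correlation for the stochastic
#'   scenarios (default 0.5).
#' @return A [reallocation_scenario()].
#' @export
#' @examples
#' demo_scenario("variance_decreasing")
demo_scenario <- function(which = c("deterministic", "variance_decreasing",
                                    "variance_increasing"),
                          rho = 0.5) {
  which <- match.arg(which)
  means <- list(A = c(100000, 150), a = c(40000, 90),
                B = c(140000, 50), b = c(70000, 30))
  if (which == "deterministic") {
    return(reallocation_scenario(
      A = program("Program A", means$A[1], means$A[2]),
      a = program("Program a", means$a[1], means$a[2]),
      B = program("Program B", means$B[1], means$B[2]),
      b = program("Program b", means$b[1], means$b[2])
    ))
  }
  # SD pattern: the "tight" pair gets 5000 kUSD / 5 LY, the "wide" pair
  # 13,000 kUSD / 13 LY; which pair is tight flips between the scenarios.
  tight <- c(5000, 5)
  wide <- c(13000, 13)
  sds <- if (which == "variance_decreasing") {
    list(A = tight, a = wide, B = wide, b = tight)
  } else {
    list(A = wide, a = tight, B = tight, b = wide)
  }
  progs <- lapply(c(A = "A", a = "a", B = "B", b = "b"), function(nm) {
    program_dist(paste("Program", nm),
                 mean_cost = means[[nm]][1], sd_cost = sds[[nm]][1],
                 mean_effect = means[[nm]][2], sd_effect = sds[[nm]][2],
                 rho = rho)
  })
  reallocation_scenario(A = progs$A, a = progs$a, B = progs$B, b = progs$b)
}

#' Read a reallocation scenario from a YAML or JSON config file
#'
#' The file holds one block per program under `programs:` with keys `A`,
#' `a`, `B`, `b`. Each block gives `label` (optional), and either
#' `cost`/`effect` (deterministic) or `mean_cost`/`sd_cost`/`mean_effect`/
#' `sd_effect` plus optional `rho` (default 0.5). Costs are in thousand USD,
#' effects in life years. Packaged examples live in
#' `system.file("extdata", package = "dmplane")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [reallocation_scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$programs)) {
    stop("config must contain a `programs` block", call. = FALSE)
  }
  missing <- setdiff(c("A", "a", "B", "b"), names(cfg$programs))
  if (length(missing)) {
    stop("config `programs` block is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  build <- function(block, nm) {
    label <- block$label %||% paste("Program", nm)
    if (!is.null(block$mean_cost)) {
      program_dist(label,
                   mean_cost = block$mean_cost,
                   sd_cost = block$sd_cost %||% 0,
                   mean_effect = block$mean_effect,
                   sd_effect = block$sd_effect %||% 0,
                   rho = block$rho %||% 0.5)
    } else {
      program(label, cost = block$cost, effect = block$effect)
    }
  }
  progs <- lapply(c(A = "A", a = "a", B = "B", b = "b"),
                  function(nm) build(cfg$programs[[nm]], nm))
  reallocation_scenario(A = progs$A, a = progs$a, B = progs$B, b = progs$b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
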