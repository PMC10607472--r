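# packaged datasets: name -> (file, md5). The checksum is verified at every
# load so fixture values cannot drift silently.
.fixture_catalog <- list(
  pupal_development_points = list(
    file = "pupal_development_points.csv",
    md5 = "b2ccc435c8432cf91397bc5bb1c47c3a"),
  sdt_model_params = list(
    file = "sdt_model_params.csv",
    md5 = "c25cc2ea7997b6f913caf5d5b07172ab"),
  pupal_model_params = list(
    file = "pupal_model_params.csv",
    md5 = "01fc95322dcd09a2a51b4cc7e75efb03"),
  stage_dd_constants = list(
    file = "stage_dd_constants.csv",
    md5 = "c7bb92dd4d5e4eb770f406fb6afe6074"),
  lower_thresholds = list(
    file = "lower_thresholds.csv",
    md5 = "bf0ef01719d20fdca96b6bbd0d8f4db9"),
  emergence_1986 = list(
    file = "emergence_1986.csv",
    md5 = "9563b3f6e6c97c943eb47c5f0fde9d9c"),
  emergence_1987 = list(
    file = "emergence_1987.csv",
    md5 = "86f7a2fbacf63af556d1243457a81ebb"))

#' List the packaged datasets
#'
#' @return Character vector of fixture names accepted by [load_fixture()].
#' @examples
#' list_fixtures()
#' @export
list_fixtures <- function() names(.fixture_catalog)

#' Load a packaged dataset
#'
#' Returns one of the small reference datasets shipped with the package:
#' `pupal_development_points` (17 constant-temperature development times of
#' non-diapausing pupae from three published laboratory studies, with a
#' `source` column), `sdt_model_params` / `pupal_model_params` (reference
#' Lactin and Weibull parameter estimates for the two phases),
#' `stage_dd_constants` (per-stage thermal constants above the common base
#' temperature), `lower_thresholds` (published stage-specific lower
#' developmental thresholds) and `emergence_1986` / `emergence_1987`
#' (observed and model-predicted Julian dates of cumulative adult emergence
#' from field cohorts of summer-diapausing pupae). File content is
#' checksum-verified at load.
#'
#' @param name Fixture name; see [list_fixtures()].
#' @return A data frame.
#' @examples
#' load_fixture("stage_dd_constants")
#' @export
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.fixture_catalog))
    stop("unknown fixture '", paste(name, collapse = ","), "'; available: ",
         paste(list_fixtures(), collapse = ", "), call. = FALSE)
  entry <- .fixture_catalog[[name]]
  path <- system.file("extdata", entry$file, package = "onionfly",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, entry$md5))
    stop("fixture '", name, "' failed its checksum (got ", md5,
         "); packaged data may be corrupted", call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run the built-in reference scenarios
#'
#' Recomputes, from the packaged fixtures and the package's own functions,
#' the desk-scale reference quantities distributed with the package and
#' reports computed versus expected values with a pass flag: the common
#' base temperature; the generation degree-day totals (egg-to-egg,
#' adult-to-pupa, the backward-tracking constant, one day at 23 degrees C);
#' the Lactin refit of the 17 pupal development points (R-squared and
#' thermal maximum); the upper temperature limit of the
#' diapause-termination curve; the completion proportion at the Weibull
#' transition centre; and the observed-vs-predicted discrepancy statistics
#' of the 1986/1987 field emergence cohorts. Failures are reported in the
#' table, never raised.
#'
#' @param scenarios Optional character vector restricting the run to a
#'   subset of scenario names; `character(0)` gives an empty report.
#' @return A data frame with columns `scenario`, `computed`, `expected`,
#'   `tolerance`, `pass`.
#' @examples
#' run_reference_scenarios(c("common_base_temperature", "dd_egg_to_egg"))
#' @export
run_reference_scenarios <- function(scenarios = NULL) {
  runs <- list(
    common_base_temperature = function() {
      c(common_base_temperature(load_fixture("lower_thresholds")$threshold),
        3.9, 1e-9)
    },
    dd_egg_to_egg = function() {
      c(stage_constants()$egg_to_egg, 650.9, 1e-9)
    },
    dd_adult_to_pupa = function() {
      c(stage_constants()$adult_to_pupa, 433.9, 1e-9)
    },
    dd_backtrack = function() {
      c(stage_constants()$backtrack, 414.8, 1e-9)
    },
    dd_one_day_23c = function() {
      c(thermal_constant(1, 23, 3.9), 19.1, 1e-9)
    },
    pupal_lactin_r_squared = function() {
      dev <- load_fixture("pupal_development_points")
      c(fit_lactin(dev$temperature, 1 / dev$days)$r.squared, 0.94, 0.01)
    },
    pupal_lactin_t_max = function() {
      dev <- load_fixture("pupal_development_points")
      c(unname(coef(fit_lactin(dev$temperature, 1 / dev$days))["t_max"]),
        37.89, 1)
    },
    sdt_upper_limit = function() {
      c(lactin_upper_limit(sdt_defaults()$rate), 22.1, 0.05)
    },
    sdt_completion_at_alpha = function() {
      d <- sdt_defaults()$dist
      c(100 * weibull_cdf(d$alpha, d), 63.2, 0.05)
    },
    comparison_1986_mean = function() {
      tab <- load_fixture("emergence_1986")
      cmp <- compare_emergence(data.frame(percent = tab$percent,
                                          julian = tab$observed),
                               data.frame(percent = tab$percent,
                                          julian = tab$predicted),
                               percentiles = tab$percent)
      c(cmp$mean_difference, 7.64, 0.005)
    },
    comparison_1986_se = function() {
      tab <- load_fixture("emergence_1986")
      cmp <- compare_emergence(data.frame(percent = tab$percent,
                                          julian = tab$observed),
                               data.frame(percent = tab$percent,
                                          julian = tab$predicted),
                               percentiles = tab$percent)
      c(cmp$se, 0.7296, 5e-5)
    },
    comparison_1987_mean = function() {
      tab <- load_fixture("emergence_1987")
      cmp <- compare_emergence(data.frame(percent = tab$percent,
                                          julian = tab$observed),
                               data.frame(percent = tab$percent,
                                          julian = tab$predicted),
                               percentiles = tab$percent)
      c(cmp$mean_difference, 4.79, 0.005)
    })
  if (is.null(scenarios)) scenarios <- names(runs)
  bad <- setdiff(scenarios, names(runs))
  if (length(bad))
    stop("unknown scenario(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(scenarios) == 0L)
    return(data.frame(scenario = character(0), computed = numeric(0),
                      expected = numeric(0), tolerance = numeric(0),
                      pass = logical(0)))
  rows <- lapply(scenarios, function(nm) {
    v <- tryCatch(runs[[nm]](), error = function(e) c(NA_real_, NA_real_, NA_real_))
    data.frame(scenario = nm, computed = v[1L], expected = v[2L],
               tolerance = v[3L],
               pass = is.finite(v[1L]) && abs(v[1L] - v[2L]) <= v[3L])
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
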