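# Registry of CRL -> GA dating formulae.
#
# All formulae are normalised at registration to take CRL in cm and return
# GA in decimal weeks, whatever convention the source publication used
# (CRL in mm, GA in days). The raw convention is kept in the registry
# entry so users can audit the transcription.

.formula_registry <- new.env(parent = emptyenv())

#' Register a CRL-to-GA dating formula
#'
#' Adds a formula to the package-wide registry used by [predict_ga()],
#' [invert_formula()] and all downstream comparison machinery. The
#' supplied function is evaluated in the source publication's units and
#' wrapped so that registry callers always work in cm and decimal weeks.
#'
#' Registration is rejected when the formula is not strictly increasing
#' in CRL over `valid_crl_range` (checked numerically on a 1000-point
#' grid): GA dating requires an invertible growth law.
#'
#' @param id Character scalar, unique formula identifier (e.g.
#'   `"garbhini_ga1"`).
#' @param fun Function of one argument: CRL in `crl_unit`, returning GA
#'   in `ga_unit`.
#' @param valid_crl_range Numeric length-2, CRL validity range in cm.
#' @param source Citation string for the coefficients.
#' @param crl_unit `"cm"` or `"mm"` — the unit `fun` expects.
#' @param ga_unit `"weeks"` or `"days"` — the unit `fun` returns.
#' @param coefficients Optional named numeric vector, recorded verbatim
#'   for provenance.
#' @param overwrite Allow replacing an existing entry (default `FALSE`;
#'   duplicate ids are otherwise an error).
#' @return The registry entry, invisibly.
#' @examples
#' register_formula("toy_linear", function(crl) 6 + crl,
#'                  valid_crl_range = c(0, 10), source = "example")
#' predict_ga("toy_linear", 2) # 8
#' @export
register_formula <- function(id, fun, valid_crl_range, source = "unspecified",
                             crl_unit = c("cm", "mm"),
                             ga_unit = c("weeks", "days"),
                             coefficients = NULL, overwrite = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.function(fun))
  stopifnot(is.numeric(valid_crl_range), length(valid_crl_range) == 2L,
            valid_crl_range[1] < valid_crl_range[2])
  crl_unit <- match.arg(crl_unit)
  ga_unit <- match.arg(ga_unit)
  if (!overwrite && exists(id, envir = .formula_registry, inherits = FALSE)) {
    stop("formula id '", id, "' already registered; use overwrite = TRUE")
  }
  crl_scale <- if (crl_unit == "mm") 10 else 1
  ga_scale <- if (ga_unit == "days") 1 / 7 else 1
  fn_cm_weeks <- function(crl_cm) ga_scale * fun(crl_scale * crl_cm)

  grid <- seq(valid_crl_range[1], valid_crl_range[2], length.out = 1000L)
  ga <- fn_cm_weeks(grid)
  if (any(!is.finite(ga)) || any(ga <= 0)) {
    stop("formula '", id, "' is not finite and positive over its declared range")
  }
  if (any(diff(ga) <= 0)) {
    stop("formula '", id, "' is not strictly increasing over its declared ",
         "CRL range; registration rejected")
  }
  entry <- list(id = id, fn = fn_cm_weeks, valid_crl_range = valid_crl_range,
                source = source, crl_unit = crl_unit, ga_unit = ga_unit,
                coefficients = coefficients)
  assign(id, entry, envir = .formula_registry)
  invisible(entry)
}

#' List registered dating formulae
#'
#' @param details If `TRUE` return the full registry entries; otherwise a
#'   character vector of ids.
#' @return Character vector of ids, or named list of entries.
#' @export
ga_formulae <- function(details = FALSE) {
  ids <- sort(ls(envir = .formula_registry))
  if (!details) return(ids)
  setNames(lapply(ids, get, envir = .formula_registry), ids)
}

get_formula <- function(formula_id) {
  if (!exists(formula_id, envir = .formula_registry, inherits = FALSE)) {
    stop("unknown formula id '", formula_id, "'; available: ",
         paste(ga_formulae(), collapse = ", "))
  }
  get(formula_id, envir = .formula_registry, inherits = FALSE)
}

#' Estimate gestational age from crown-rump length
#'
#' Dispatches to a registered dating formula. CRL above the formula's
#' declared validity range is evaluated with a warning rather than an
#' error, because truncation supplementation deliberately uses the
#' 15-18 week tail of the Hadlock relation (see
#' [supplement_truncated()]). Negative CRL is a domain error.
#'
#' @param formula_id Registered formula id; see [ga_formulae()].
#' @param crl_cm Numeric vector of CRL in cm.
#' @param warn_out_of_range Warn when CRL exceeds the declared range.
#' @return GA in decimal weeks, same length as `crl_cm`.
#' @examples
#' predict_ga("garbhini_ga1", c(1, 5, 8))
#' @export
predict_ga <- function(formula_id, crl_cm, warn_out_of_range = TRUE) {
  entry <- get_formula(formula_id)
  stopifnot(is.numeric(crl_cm))
  if (any(crl_cm < 0, na.rm = TRUE)) {
    stop("negative CRL is outside the domain of any dating formula")
  }
  out_hi <- !is.na(crl_cm) & crl_cm > entry$valid_crl_range[2]
  if (warn_out_of_range && any(out_hi)) {
    warning(sum(out_hi), " CRL value(s) above the declared range ",
            "[", entry$valid_crl_range[1], ", ", entry$valid_crl_range[2],
            "] cm for '", formula_id, "'; evaluated anyway")
  }
  entry$fn(crl_cm)
}

#' Garbhini-GA1 first-trimester dating formula
#'
#' The population-specific quadratic developed on the GARBH-Ini North
#' Indian cohort:
#' \deqn{GA = -0.02294\,CRL^2 + 1.15018\,CRL + 6.73526}
#' with CRL in cm and GA in decimal weeks.
#'
#' @param crl_cm Numeric vector of CRL in cm.
#' @param warn_out_of_range Warn when CRL exceeds 10 cm.
#' @return GA in decimal weeks.
#' @examples
#' predict_ga_garbhini(0)    # 6.73526, the intercept
#' predict_ga_garbhini(1)    # 7.8625
#' @export
predict_ga_garbhini <- function(crl_cm, warn_out_of_range = TRUE) {
  predict_ga("garbhini_ga1", crl_cm, warn_out_of_range = warn_out_of_range)
}

#' Invert a dating formula: CRL from GA
#'
#' Solves `predict_ga(formula_id, crl) == ga_weeks` for CRL by bisection
#' over the formula's declared range (formulae are registered strictly
#' increasing, so the root is unique). Used by the synthetic cohort
#' generator and by truncation supplementation; `extend_cm` allows
#' solving above the declared range where the underlying expression is
#' still monotone (e.g. Hadlock at 15-18 weeks).
#'
#' @param formula_id Registered formula id.
#' @param ga_weeks Numeric vector of GA in decimal weeks.
#' @param extend_cm Extend the search interval this many cm above the
#'   declared upper bound (default 0).
#' @param tol Absolute tolerance on GA, in weeks.
#' @return CRL in cm such that the forward formula reproduces `ga_weeks`
#'   within `tol`.
#' @examples
#' invert_formula("garbhini_ga1", 6.73526) # 0
#' @export
invert_formula <- function(formula_id, ga_weeks, extend_cm = 0, tol = 1e-9) {
  entry <- get_formula(formula_id)
  lo <- entry$valid_crl_range[1]
  hi <- entry$valid_crl_range[2] + extend_cm
  ga_lo <- entry$fn(lo)
  ga_hi <- entry$fn(hi)
  vapply(ga_weeks, function(g) {
    if (!is.finite(g)) return(NA_real_)
    if (g < ga_lo - tol || g > ga_hi + tol) {
      stop("GA ", format(g), " weeks is outside the attainable range [",
           format(ga_lo), ", ", format(ga_hi), "] of '", formula_id, "'")
    }
    if (abs(g - ga_lo) <= tol) return(lo)
    if (abs(g - ga_hi) <= tol) return(hi)
    uniroot(function(x) entry$fn(x) - g, lower = lo, upper = hi,
            tol = 1e-12)$root
  }, numeric(1))
}

#' Export / import the formula registry as YAML
#'
#' The YAML file records id, coefficients, units, validity range and
#' citation for every registered formula, giving users a config override
#' path: edit the file and re-import to correct or replace any entry.
#' Only formulae registered from coefficient tables (the built-ins) are
#' re-importable; entries registered from opaque R functions are exported
#' for documentation but skipped with a warning on import.
#'
#' @param path File path.
#' @return `export_formulae` returns `path` invisibly; `import_formulae`
#'   returns the ids imported.
#' @export
export_formulae <- function(path) {
  entries <- ga_formulae(details = TRUE)
  out <- lapply(entries, function(e) {
    list(id = e$id, source = e$source, crl_unit = e$crl_unit,
         ga_unit = e$ga_unit, valid_crl_range_cm = e$valid_crl_range,
         coefficients = as.list(e$coefficients))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname export_formulae
#' @export
import_formulae <- function(path) {
  defs <- yaml::read_yaml(path)
  imported <- character(0)
  for (d in defs) {
    builder <- .builtin_builders[[d$id]]
    if (is.null(builder)) {
      warning("no coefficient template for '", d$id, "'; skipped")
      next
    }
    co <- unlist(d$coefficients)
    register_formula(d$id, builder(co),
                     valid_crl_range = as.numeric(d$valid_crl_range_cm),
                     source = d$source, crl_unit = d$crl_unit,
                     ga_unit = d$ga_unit, coefficients = co,
                     overwrite = TRUE)
    imported <- c(imported, d$id)
  }
  invisible(imported)
}

# Builders map a named coefficient vector to the source-unit function;
# shared between built-in registration and YAML re-import.
.builtin_builders <- list(
  garbhini_ga1 = function(co) function(crl)
    co[["a2"]] * crl^2 + co[["a1"]] * crl + co[["a0"]],
  hadlock = function(co) function(crl)
    exp(co[["b0"]] + co[["b1"]] * crl + co[["b2"]] * crl^2 +
        co[["b3"]] * crl^3 + co[["b4"]] * crl^4),
  robinson_fleming = function(co) function(crl)
    co[["a"]] * sqrt(crl) + co[["b"]],
  mclennan_schluter = function(co) function(crl)
    co[["a0"]] + co[["a1"]] * crl + co[["a2"]] * crl^2,
  sahota = function(co) function(crl)
    co[["a"]] + co[["b"]] * sqrt(crl),
  verburg = function(co) function(crl)
    exp(co[["b0"]] + co[["b1"]] * crl + co[["b2"]] * log(crl)),
  intergrowth21 = function(co) function(crl)
    co[["a"]] + co[["b"]] * sqrt(crl) + co[["c"]] * crl
)

# Built-in comparator coefficients are transcribed from the original
# publications (unit convention recorded per entry). The authors'
# supplementary coefficient table is not public, so these entries are
# best-effort and provisional: use export_formulae()/import_formulae()
# to override any of them.
register_builtin_formulae <- function() {
  reg <- function(id, co, range_cm, source, crl_unit, ga_unit) {
    register_formula(id, .builtin_builders[[id]](co),
                     valid_crl_range = range_cm, source = source,
                     crl_unit = crl_unit, ga_unit = ga_unit,
                     coefficients = co, overwrite = TRUE)
  }
  reg("garbhini_ga1",
      c(a2 = -0.02294, a1 = 1.15018, a0 = 6.73526), c(0, 10),
      "Garbhini-GA1, GARBH-Ini cohort quadratic (CRL cm -> GA weeks)",
      "cm", "weeks")
  reg("hadlock",
      c(b0 = 1.684969, b1 = 0.315646, b2 = -0.049306, b3 = 0.004057,
        b4 = -0.000120456), c(0, 13),
      "Hadlock et al. 1992, Radiology 182:501-505 (CRL cm -> GA weeks)",
      "cm", "weeks")
  reg("robinson_fleming",
      c(a = 8.052, b = 23.73), c(0.1, 12),
      "Robinson & Fleming 1975, BJOG 82:702-710 (CRL mm -> GA days)",
      "mm", "days")
  reg("mclennan_schluter",
      c(a0 = 5.2876, a1 = 0.1584, a2 = -0.0007), c(0, 11),
      "McLennan & Schluter 2008, ANZJOG 48:173-179 (CRL mm -> GA weeks); provisional transcription",
      "mm", "weeks")
  reg("sahota",
      c(a = 26.643, b = 7.822), c(0.1, 12),
      "Sahota et al. 2009, Fetal Diagn Ther 26:53-57 (CRL mm -> GA days)",
      "mm", "days")
  reg("verburg",
      c(b0 = 1.4653, b1 = 0.001737, b2 = 0.2313), c(0.1, 12),
      "Verburg et al. 2008, Ultrasound Obstet Gynecol 31:388-396 (CRL mm -> GA weeks)",
      "mm", "weeks")
  reg("intergrowth21",
      c(a = 40.9041, b = 3.21585, c = 0.348956), c(0, 10),
      "Papageorghiou et al. 2014, INTERGROWTH-21st dating standard (CRL mm -> GA days)",
      "mm", "days")
  invisible(NULL)
}

#' Reset the formula registry to the built-in set
#'
#' Drops user-registered formulae and restores the seven shipped entries.
#' Mostly useful in tests.
#' @return Invisibly, the ids now registered.
#' @export
reset_formulae <- function() {
  rm(list = ls(envir = .formula_registry), envir = .formula_registry)
  register_builtin_formulae()
  invisible(ga_formulae())
}

.onLoad <- function(libname, pkgname) {
  register_builtin_formulae()
}
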