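#' Base-case run configuration
#'
#' Returns the full model configuration as a nested list: epidemiology
#' (mutation prevalence, test sensitivity/specificity, unknown-result
#' rate), per-regimen cycle costs split into administration and
#' non-administration phases (USD, 2014 prices), health-state utilities and
#' adverse-event disutility burdens, cycle settings (60 monthly cycles, 3%
#' annual discount), the extrapolation method, and the pathway definitions
#' binding each treatment line to a PFS and an OS curve set.
#'
#' Pathways: test-positive patients receive first-line erlotinib then
#' second-line cisplatin+pemetrexed; test-negative and test-unknown
#' patients receive first-line cisplatin+pemetrexed then second-line
#' docetaxel; the no-testing cohort receives first-line
#' cisplatin+pemetrexed then second-line erlotinib. Every pathway ends in
#' best supportive care. Because no trial reports overall survival for
#' first-line erlotinib in mutation-positive patients, that line's OS is
#' bound to the pooled first-line cisplatin+gemcitabine OS of unselected
#' patients, and first-line chemotherapy OS in mutation-negative patients
#' to the pooled OS of all patients in the no-testing strategy — both are
#' ordinary curve bindings that scenarios may override.
#'
#' The adverse-event burden per regimen is the sum over grade 3-4 events of
#' incidence times per-event disutility; the incidences are package
#' assumptions (see the methods vignette) since only the per-event
#' disutilities are published.
#'
#' @return A named list; see [validate_config()] for the constraints.
#' @export
default_config <- function() {
  list(
    epidemiology = list(
      prevalence = 0.39,
      sensitivity = 0.984,
      specificity = 0.892,
      p_unknown = 0.11
    ),
    test_cost = 104,
    cycles = list(
      horizon = 60L,
      annual_discount_rate = 0.03,
      half_cycle_correction = FALSE
    ),
    costs = list(
      ert  = list(admin = 2113, nonadmin = 2113, admin_cycles = Inf),
      cpem = list(admin = 4157, nonadmin = 503,  admin_cycles = 4),
      cgem = list(admin = 3327, nonadmin = 454,  admin_cycles = 4),
      dox  = list(admin = 3300, nonadmin = 616,  admin_cycles = 4),
      pem  = list(admin = 4501, nonadmin = 594,  admin_cycles = 4),
      bsc  = list(admin = 1038, nonadmin = 1038, admin_cycles = Inf)
    ),
    utilities = list(
      pre_progression = 0.6532,
      post_progression = 0.4734,
      bsc = 0.4734,
      oral_adjustment = 0.02,
      iv_disutility = 0.043,
      iv_disutility_applied = FALSE
    ),
    # sum over grade 3-4 events of assumed incidence x published disutility
    ae_burden = list(ert = 0.010, cpem = 0.028, cgem = 0.033,
                     dox = 0.042, pem = 0.016, bsc = 0),
    ae_whole_period = FALSE,
    oral_regimens = "ert",
    extrapolation = "mean",
    pathways = list(
      test_positive = list(
        list(regimen = "ert",  pfs = "pfs_ert1_mpos",  os = "os_cgem1_all"),
        list(regimen = "cpem", pfs = "pfs_cpem2_mpos", os = "os_cpem2_mpos")
      ),
      test_negative = list(
        list(regimen = "cpem", pfs = "pfs_cpem1_mneg", os = "os_cpem1_all"),
        list(regimen = "dox",  pfs = "pfs_dox2_mneg",  os = "os_dox2_mneg")
      ),
      no_testing = list(
        list(regimen = "cpem", pfs = "pfs_cpem1_all",  os = "os_cpem1_all"),
        list(regimen = "ert",  pfs = "pfs_ert2_all",   os = "os_ert2_all")
      )
    ),
    bsc_curve = "os_bsc"
  )
}

prob_keys <- c("epidemiology.prevalence", "epidemiology.sensitivity",
               "epidemiology.specificity", "epidemiology.p_unknown")

get_by_path <- function(x, path) {
  for (k in strsplit(path, ".", fixed = TRUE)[[1L]]) x <- x[[k]]
  x
}

set_by_path <- function(x, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  if (length(keys) == 1L) {
    x[[keys]] <- value
  } else {
    x[[keys[1L]]] <- set_by_path(x[[keys[1L]]], paste(keys[-1L], collapse = "."),
                                 value)
  }
  x
}

#' Validate a run configuration
#'
#' Collects all violations — probabilities outside [0, 1], negative costs,
#' bad horizon or discount rate, pathway lines referencing an unknown
#' regimen, unknown extrapolation method — and reports them together.
#'
#' @param config a configuration list as returned by [default_config()].
#' @return `config`, invisibly, if valid; otherwise an error listing every
#'   problem found.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)

  for (key in prob_keys) {
    v <- tryCatch(get_by_path(config, key), error = function(e) NULL)
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v)) {
      add(paste0(key, ": missing or not a number"))
    } else if (v < 0 || v > 1) {
      add(paste0(key, ": ", v, " outside [0, 1]"))
    }
  }
  if (is.null(config$test_cost) || config$test_cost < 0) {
    add("test_cost: missing or negative")
  }
  cy <- config$cycles
  if (is.null(cy$horizon) || cy$horizon < 1) add("cycles.horizon: must be >= 1")
  if (is.null(cy$annual_discount_rate) || cy$annual_discount_rate < 0) {
    add("cycles.annual_discount_rate: must be >= 0")
  }
  for (rg in names(config$costs)) {
    cc <- config$costs[[rg]]
    if (any(unlist(cc[c("admin", "nonadmin")]) < 0)) {
      add(paste0("costs.", rg, ": negative cost"))
    }
    if (is.null(cc$admin_cycles) || cc$admin_cycles < 0) {
      add(paste0("costs.", rg, ".admin_cycles: must be >= 0"))
    }
  }
  for (u in c("pre_progression", "post_progression", "bsc")) {
    v <- config$utilities[[u]]
    if (is.null(v) || v < 0 || v > 1) {
      add(paste0("utilities.", u, ": outside [0, 1]"))
    }
  }
  for (rg in names(config$ae_burden)) {
    if (config$ae_burden[[rg]] < 0) add(paste0("ae_burden.", rg, ": negative"))
  }
  if (!config$extrapolation %in% c("mean", "regression", "least_squares")) {
    add(paste0("extrapolation: '", config$extrapolation,
               "' not one of mean, regression, least_squares"))
  }
  for (pw in names(config$pathways)) {
    lines <- config$pathways[[pw]]
    if (length(lines) < 1) add(paste0("pathways.", pw, ": empty"))
    for (i in seq_along(lines)) {
      ln <- lines[[i]]
      if (is.null(ln$regimen) || !ln$regimen %in% names(config$costs)) {
        add(paste0("pathways.", pw, "[", i, "]: regimen '", ln$regimen,
                   "' has no cost entry"))
      }
      if (is.null(ln$pfs) || is.null(ln$os)) {
        add(paste0("pathways.", pw, "[", i, "]: needs pfs and os bindings"))
      }
    }
  }
  if (is.null(config$bsc_curve)) add("bsc_curve: missing")

  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(config)
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @return `load_config()` returns the validated configuration list with
#'   attribute `hash` (see [config_hash()]); `write_config()` returns
#'   `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  config <- yaml::read_yaml(path)
  validate_config(config)
  attr(config, "hash") <- config_hash(config)
  config
}

#' @param config a configuration list.
#' @rdname load_config
#' @export
write_config <- function(config, path) {
  attr(config, "hash") <- NULL
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Hash of a resolved configuration
#'
#' Embedded in every report so results can be traced to the exact inputs
#' that produced them.
#'
#' @param config a configuration list.
#' @return character scalar hash.
#' @export
config_hash <- function(config) {
  attr(config, "hash") <- NULL
  rlang::hash(config)
}

# Deep merge for scenario overrides: named lists recurse, anything else
# (including unnamed lists, e.g. whole pathway definitions) replaces
# wholesale. Unknown top-level keys error.
merge_config <- function(config, overrides) {
  if (length(overrides) == 0) return(config)
  bad <- setdiff(names(overrides), names(config))
  if (length(bad)) {
    stop("unknown override key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(names(config), collapse = ", "),
         call. = FALSE)
  }
  deep <- function(base, ov) {
    if (!is.list(base) || !is.list(ov) ||
        is.null(names(ov)) || any(names(ov) == "")) {
      return(ov)
    }
    for (k in names(ov)) {
      base[[k]] <- if (k %in% names(base)) deep(base[[k]], ov[[k]]) else ov[[k]]
    }
    base
  }
  deep(config, overrides)
}
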