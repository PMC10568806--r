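#' Path of the packaged baseline parameter configuration
#'
#' The shipped configuration mirrors the published input table column for
#' column: baseline value, deterministic range, and the beta/gamma sampling
#' parameters with the (mean, SE) pairs they derive from.
#'
#' @return file path of the YAML configuration.
#' @export
default_config_path <- function() {
  system.file("extdata", "table1_baseline.yaml", package = "psmcea",
              mustWork = TRUE)
}

leaf_base <- function(x) if (is.list(x)) x$base else x

# recursive merge: user values override defaults; missing leaves collected
merge_config <- function(default, user, prefix = "", missing = NULL) {
  if (!is.list(default)) {
    return(list(value = if (is.null(user)) default else user,
                missing = missing))
  }
  out <- default
  for (nm in names(default)) {
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.null(user[[nm]])) {
      missing <- c(missing, key)
    } else if (is.list(default[[nm]]) && !("base" %in% names(default[[nm]]))) {
      res <- merge_config(default[[nm]], user[[nm]], key, missing)
      out[[nm]] <- res$value
      missing <- res$missing
    } else {
      out[[nm]] <- user[[nm]]
    }
  }
  list(value = out, missing = missing)
}

#' Load and validate the model parameter configuration
#'
#' Reads a YAML configuration (the packaged baseline when \code{path} is
#' NULL), validates every field against its invariant (probabilities and
#' utilities in [0, 1], non-negative costs, discount rate within its
#' admissible range, regimen mixtures summing to one), renormalises
#' mixtures that are off by rounding (with a logged note), and assembles
#' the sampling registry for sensitivity analyses.  When a partial user
#' configuration is supplied, absent sections fall back to the packaged
#' baseline with a warning naming them.
#'
#' @param path YAML file, or NULL for the packaged baseline.
#' @param quiet suppress informational notes (not warnings/errors).
#' @return an object of class \code{cea_params}; the sensitivity registry
#'   is available through \code{\link{param_registry}}.
#' @examples
#' params <- load_config(quiet = TRUE)
#' params$utility$pfs
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  default <- yaml::read_yaml(default_config_path())
  if (is.null(path)) {
    cfg <- default
  } else {
    user <- yaml::read_yaml(path)
    res <- merge_config(default, user)
    cfg <- res$value
    if (length(res$missing) > 0) {
      warning("configuration fields missing, using packaged defaults: ",
              paste(res$missing, collapse = ", "), call. = FALSE)
    }
  }
  build_params(cfg, quiet = quiet)
}

#' @rdname load_config
#' @export
default_model_params <- function(quiet = TRUE) load_config(quiet = quiet)

named_base_vec <- function(node) {
  vapply(node, leaf_base, 0)
}

build_params <- function(cfg, quiet = FALSE) {
  note <- function(...) if (!quiet) message(...)
  p <- list(
    cycle_days = cfg$model$cycle_days,
    discount_rate = leaf_base(cfg$model$discount_rate),
    wtp = cfg$model$wtp,
    horizon_threshold = cfg$model$horizon$survival_threshold,
    horizon_cap_years = cfg$model$horizon$cap_years,
    integration = cfg$model$integration %||% "trapezoid",
    bsa = leaf_base(cfg$patient$bsa),
    weight = cfg$patient$weight,
    utility = list(pfs = leaf_base(cfg$utility$pfs),
                   pd = leaf_base(cfg$utility$pd)),
    ae = list(
      incidence = list(P = named_base_vec(cfg$ae$incidence$P),
                       C = named_base_vec(cfg$ae$incidence$C)),
      cost = named_base_vec(cfg$ae$cost),
      disutility = named_base_vec(cfg$ae$disutility)),
    prices = named_base_vec(cfg$prices),
    admin_cost = leaf_base(cfg$costs$administration),
    followup_cost = leaf_base(cfg$costs$followup),
    bsc_cost = leaf_base(cfg$costs$bsc),
    firstline_mix_C = unlist(cfg$mixes$firstline_C),
    subsequent_mix = list(P = named_base_vec(cfg$mixes$subsequent$P),
                          C = named_base_vec(cfg$mixes$subsequent$C)),
    ici_cap_cycles = cfg$subsequent_ici_cap_cycles,
    pap = cfg$pap,
    dosing = cfg$dosing)

  # --- validation -----------------------------------------------------
  chk_prob <- function(value, field) {
    if (any(!is.finite(value)) || any(value < 0) || any(value > 1)) {
      stop("invalid configuration: ", field, " must lie in [0, 1]",
           call. = FALSE)
    }
  }
  chk_nonneg <- function(value, field) {
    if (any(!is.finite(value)) || any(value < 0)) {
      stop("invalid configuration: ", field, " must be >= 0", call. = FALSE)
    }
  }
  chk_prob(p$utility$pfs, "utility.pfs")
  chk_prob(p$utility$pd, "utility.pd")
  chk_prob(p$ae$incidence$P, "ae.incidence.P")
  chk_prob(p$ae$incidence$C, "ae.incidence.C")
  chk_prob(-p$ae$disutility, "ae.disutility (negated)")
  chk_nonneg(p$ae$cost, "ae.cost")
  chk_nonneg(p$prices, "prices")
  chk_nonneg(c(p$admin_cost, p$followup_cost, p$bsc_cost), "costs")
  chk_nonneg(c(p$pap$annual_cost, p$pap$cap_total), "pap")
  if (p$discount_rate < 0 || p$discount_rate > 0.08) {
    stop("invalid configuration: model.discount_rate must lie in [0, 0.08]",
         call. = FALSE)
  }
  if (p$cycle_days <= 0 || p$horizon_threshold <= 0 ||
      p$horizon_cap_years <= 0 || p$bsa <= 0 || p$weight <= 0) {
    stop("invalid configuration: cycle, horizon, bsa and weight must be > 0",
         call. = FALSE)
  }
  for (mx in list(c("firstline_mix_C"), c("subsequent_mix", "P"),
                  c("subsequent_mix", "C"))) {
    w <- get_path(p, mx)
    chk_prob(w, paste(mx, collapse = "."))
    if (abs(sum(w) - 1) > 1e-6) {
      note("mixture ", paste(mx, collapse = "."), " sums to ",
           format(sum(w)), "; renormalising to 1")
      p <- assign_path(p, mx, w / sum(w))
    }
  }

  structure(p, class = "cea_params",
            registry = build_registry(cfg, quiet = quiet))
}

get_path <- function(x, keys) {
  for (k in keys) x <- x[[k]]
  x
}

assign_path <- function(x, keys, value) {
  if (length(keys) == 1L) {
    x[[keys]] <- value
    return(x)
  }
  x[[keys[1]]] <- assign_path(x[[keys[1]]], keys[-1], value)
  x
}

#' Set one parameter by its registry id
#'
#' @param params a \code{cea_params} object.
#' @param id dotted registry id, e.g. \code{"utility.pd"} or
#'   \code{"prices.oxaliplatin"}.
#' @param value replacement value.
#' @return modified \code{cea_params}.
#' @export
set_param <- function(params, id, value) {
  assign_path(params, strsplit(id, ".", fixed = TRUE)[[1]], value)
}

#' @rdname set_param
#' @export
get_param <- function(params, id) {
  get_path(params, strsplit(id, ".", fixed = TRUE)[[1]])
}

#' Sensitivity registry of a parameter set
#'
#' One row per input-table parameter: kind of sampling distribution (beta,
#' gamma or fixed), resolved sampling parameters, deterministic bounds, a
#' negation flag for disutilities (sampled as magnitudes) and a mixture
#' group label for weights renormalised after joint sampling.
#'
#' @param params a \code{cea_params} from \code{\link{load_config}}.
#' @return \code{data.frame} registry.
#' @export
param_registry <- function(params) attr(params, "registry")

registry_row <- function(id, node, kind_default = NULL, negate = FALSE,
                         group = NA_character_, quiet = FALSE) {
  kind <- node$dist %||% kind_default %||% "fixed"
  alpha <- node$alpha %||% NA_real_
  beta <- node$beta %||% NA_real_
  shape <- node$shape %||% NA_real_
  scale <- node$scale %||% NA_real_
  mn <- node$mean %||% NA_real_
  se <- node$se %||% NA_real_
  if (kind == "beta") {
    if (is.na(alpha) || is.na(beta)) {
      mm <- beta_from_moments(abs(mn), se)
      alpha <- mm[["alpha"]]
      beta <- mm[["beta"]]
    } else if (!is.na(mn) && !is.na(se)) {
      implied <- alpha / (alpha + beta)
      rel <- abs(implied - abs(mn)) / max(abs(mn), 1e-12)
      if (rel > 0.005 && !quiet) {
        message("note: ", id, " explicit (alpha, beta) imply mean ",
                signif(implied, 4), " vs stated ", signif(abs(mn), 4),
                " (relative mismatch ", signif(rel, 2),
                "); explicit parameters used")
      }
    }
  } else if (kind == "gamma") {
    if (is.na(shape) || is.na(scale)) {
      mm <- gamma_from_moments(mn, se)
      shape <- mm[["shape"]]
      scale <- mm[["scale"]]
    } else if (!is.na(mn) && !is.na(se)) {
      implied <- shape * scale
      rel <- abs(implied - mn) / max(mn, 1e-12)
      if (rel > 0.02 && !quiet) {
        message("note: ", id, " explicit (shape, scale) imply mean ",
                signif(implied, 4), " vs stated ", signif(mn, 4),
                "; explicit parameters used")
      }
    }
  }
  data.frame(id = id, kind = kind, base = leaf_base(node),
             dsa_low = node$min %||% NA_real_,
             dsa_high = node$max %||% NA_real_,
             alpha = alpha, beta = beta, shape = shape, scale = scale,
             mean = mn, se = se, negate = negate, group = group,
             stringsAsFactors = FALSE)
}

build_registry <- function(cfg, quiet = FALSE) {
  rows <- list()
  add <- function(id, node, ...) {
    rows[[length(rows) + 1]] <<- registry_row(id, node, quiet = quiet, ...)
  }
  add("discount_rate", cfg$model$discount_rate)
  add("bsa", cfg$patient$bsa)
  add("utility.pfs", cfg$utility$pfs)
  add("utility.pd", cfg$utility$pd)
  for (arm in c("P", "C")) {
    for (ev in names(cfg$ae$incidence[[arm]])) {
      add(paste("ae.incidence", arm, ev, sep = "."),
          cfg$ae$incidence[[arm]][[ev]])
    }
  }
  for (ev in names(cfg$ae$cost)) {
    add(paste0("ae.cost.", ev), cfg$ae$cost[[ev]])
  }
  for (ev in names(cfg$ae$disutility)) {
    add(paste0("ae.disutility.", ev), cfg$ae$disutility[[ev]],
        negate = TRUE)
  }
  for (dr in names(cfg$prices)) {
    add(paste0("prices.", dr), cfg$prices[[dr]])
  }
  add("admin_cost", cfg$costs$administration)
  add("followup_cost", cfg$costs$followup)
  add("bsc_cost", cfg$costs$bsc)
  for (arm in c("P", "C")) {
    for (cl in names(cfg$mixes$subsequent[[arm]])) {
      add(paste("subsequent_mix", arm, cl, sep = "."),
          cfg$mixes$subsequent[[arm]][[cl]],
          group = paste0("subsequent_", arm))
    }
  }
  do.call(rbind, rows)
}
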