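# End-to-end analysis: equilibrium predictions for stream waters, the
# fractionation chain, mixing fractions for droplets and air samples, TRN
# mass balance, the Gibbs-energy grid, and a structured report with a
# provenance block. Everything here is deterministic given its inputs; all
# randomness lives in the synthetic-data generator.

.md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

.bin_distance <- function(distance_m, breaks) {
  labs <- c(paste0("<=", breaks[1], "m"),
            paste0(utils::head(breaks, -1), "-",
                   utils::tail(breaks, -1), "m"),
            paste0(">", breaks[length(breaks)], "m"))
  as.character(cut(distance_m, c(-Inf, breaks, Inf), labels = labs))
}

#' Recover the mixing endmembers from a droplet table
#'
#' Fits the distance-decay mixing model
#' `d15N(d) = delta_B + (delta_A - delta_B) * exp(-d / L)` to droplet
#' delta-15N by nonlinear least squares, recovering the stream-air
#' endmember `delta_A`, the surface endmember `delta_B` and the e-folding
#' length `L`. Needs droplets at three or more distinct distances.
#'
#' @param droplets a droplet table with `distance_m` and
#'   `d15N_nh4_permil`.
#' @return A list with `delta_stream_air`, `delta_surface`,
#'   `mixing_length_m` and the `fit` object.
#' @export
#' @examples
#' camp <- generate_campaign(campaign_config(seed = 7, n_droplets = 200))
#' estimate_endmembers(camp$droplets)[c(1, 2, 3)]
estimate_endmembers <- function(droplets) {
  ok <- is.finite(droplets$d15N_nh4_permil) & is.finite(droplets$distance_m)
  d <- droplets[ok, ]
  if (length(unique(d$distance_m)) < 3) {
    stop("need droplets at >= 3 distinct distances to fit endmembers",
         call. = FALSE)
  }
  near <- mean(d$d15N_nh4_permil[d$distance_m <= min(d$distance_m) + 1e-9])
  far <- mean(d$d15N_nh4_permil[d$distance_m >= max(d$distance_m) - 1e-9])
  fit <- stats::nls(
    d15N_nh4_permil ~ B + (A - B) * exp(-distance_m / L),
    data = d,
    start = list(A = near, B = far + (far - near) * 0.5,
                 L = max(d$distance_m) / 2),
    control = stats::nls.control(maxiter = 200, warnOnly = FALSE))
  cf <- stats::coef(fit)
  list(delta_stream_air = unname(cf["A"]),
       delta_surface = unname(cf["B"]),
       mixing_length_m = unname(cf["L"]), fit = fit)
}

#' Run the full cave-nitrogen analysis
#'
#' Orchestrates every model component over a set of field tables:
#'
#' * per stream sample: equilibrium NH3(g) ppbv ([equilibrium_nh3_gas()]),
#'   TRN-corrected delta-15N where nitrate is present
#'   ([trn_mass_balance()]), and the predicted delta-15N of NH3(aq),
#'   NH3(g) and acid-trapped NH4+ from the fractionation chain;
#' * per droplet and per usable air sample: the stream-air mixing fraction
#'   with an out-of-hull flag ([mixing_fraction()]);
#' * a droplet endmember recovery fit where the table supports one;
#' * the Gibbs-energy favorability grid for both ammonia-oxidation
#'   pathways ([delta_g_grid()]).
#'
#' Rows missing required fields are reported as skipped with a reason,
#' never silently dropped; per table, analyzed + skipped equals the input
#' row count. The result is deterministic given the inputs.
#'
#' @param water,droplets,air data.frames in the [sample_tables] dialects;
#'   `droplets` and `air` may be `NULL`.
#' @param config an [analysis_config()].
#' @return A list of class `nhx_report` with elements `schema_version`,
#'   `water`, `droplets`, `air`, `endmember_fit`, `thermo`, `summary` and
#'   `provenance`.
#' @export
run_analysis <- function(water, droplets = NULL, air = NULL,
                         config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  water <- as.data.frame(water)
  if (nrow(water) == 0) stop("water table is empty", call. = FALSE)

  # --- stream waters -------------------------------------------------
  need <- c("pH", "temp_C", "nhx_uM")
  bad <- !stats::complete.cases(water[need])
  w_skip <- data.frame(
    row = which(bad),
    reason = vapply(which(bad), function(i) {
      paste0("missing ", paste(need[is.na(unlist(water[i, need]))],
                               collapse = ", "))
    }, character(1)))
  w <- equilibrium_nh3_gas(water[!bad, , drop = FALSE], config$constants)

  # delta-15N of the reduced pool feeding the chain: TRN-corrected where
  # nitrate is present, otherwise the TDN value as measured
  if (!is.null(w$d15N_TDN_permil)) {
    d_src <- w$d15N_TDN_permil
    has_no3 <- !is.null(w$no3_uM) & !is.na(w$no3_uM %||% NA) &
      !is.na(w$d15N_NO3_permil %||% NA)
    if (any(has_no3)) {
      tdn <- w$nhx_uM + w$no3_uM
      d_src[has_no3] <- trn_mass_balance(
        w$d15N_TDN_permil[has_no3], tdn[has_no3],
        w$d15N_NO3_permil[has_no3], w$no3_uM[has_no3])
    }
    w$d15N_TRN_permil <- d_src
    fs <- config$fractionation
    w$d15N_nh3_aq_permil <- apply_fractionation(d_src, fs$eps_eq, fs$mode)
    w$d15N_nh3_g_permil <- apply_fractionation(
      w$d15N_nh3_aq_permil, fs$eps_gas, fs$mode)
    w$d15N_trapped_permil <- apply_fractionation(
      apply_fractionation(w$d15N_nh3_g_permil, fs$eps_transport, fs$mode),
      fs$eps_trap, fs$mode)
  }

  # --- droplets and air: mixing fractions ----------------------------
  mix_block <- function(tab, delta_col, extra_skip = NULL) {
    if (is.null(tab) || nrow(tab) == 0) {
      return(list(analyzed = NULL,
                  skipped = data.frame(row = integer(),
                                       reason = character()),
                  n_input = if (is.null(tab)) 0L else nrow(tab)))
    }
    tab <- as.data.frame(tab)
    skip <- rep(NA_character_, nrow(tab))
    if (!is.null(extra_skip)) skip <- extra_skip(tab)
    miss <- is.na(tab[[delta_col]]) & is.na(skip)
    skip[miss] <- paste0("missing ", delta_col)
    keep <- is.na(skip)
    mx <- mixing_fraction(tab[[delta_col]][keep],
                          config$delta_stream_air, config$delta_surface)
    out <- cbind(tab[keep, , drop = FALSE],
                 f_stream_air = mx$f_A, in_hull = mx$in_hull)
    list(analyzed = out,
         skipped = data.frame(row = which(!keep),
                              reason = skip[!keep]),
         n_input = nrow(tab))
  }
  drop_block <- mix_block(droplets, "d15N_nh4_permil")
  air_block <- mix_block(air, "d15N_permil", extra_skip = function(tab) {
    ifelse(!is.na(tab$quality_flag) & tab$quality_flag == "compromised",
           "compromised sampler", NA_character_)
  })

  # --- endmember recovery fit ---------------------------------------
  emfit <- NULL
  if (!is.null(drop_block$analyzed) && nrow(drop_block$analyzed) >= 10 &&
      length(unique(drop_block$analyzed$distance_m)) >= 3) {
    emfit <- tryCatch(estimate_endmembers(drop_block$analyzed),
                      error = function(e) NULL)
    if (!is.null(emfit)) emfit$fit <- NULL # keep the report serializable
  }

  # --- Gibbs-energy favorability grid -------------------------------
  pH_axis <- seq(config$thermo_pH_range[1], config$thermo_pH_range[2],
                 length.out = config$thermo_pH_n)
  nh4_axis <- exp(seq(log(config$thermo_nh4_range_M[1]),
                      log(config$thermo_nh4_range_M[2]),
                      length.out = config$thermo_nh4_n))
  thermo <- lapply(
    list(nitrite = reaction_ammonia_to_nitrite(),
         nitrate = reaction_ammonia_to_nitrate()),
    function(rx) {
      g <- delta_g_grid(rx, pH_axis, nh4_axis, config$thermo_conditions,
                        config$constants)
      imin <- which(g == min(g), arr.ind = TRUE)[1, ]
      list(grid_kJ_mol = g,
           frac_favorable = mean(g < 0),
           min_kJ_mol = min(g),
           min_at = list(pH = pH_axis[imin[1]],
                         nh4_total_M = nh4_axis[imin[2]]))
    })

  # --- distance-binned droplet summary ------------------------------
  summary_bins <- NULL
  if (!is.null(drop_block$analyzed) && nrow(drop_block$analyzed) > 0) {
    da <- drop_block$analyzed
    da$distance_bin <- .bin_distance(da$distance_m, config$distance_bins_m)
    sp <- split(da, da$distance_bin)
    summary_bins <- do.call(rbind, lapply(names(sp), function(b) {
      g <- sp[[b]]
      data.frame(distance_bin = b, n = nrow(g),
                 median_nh4_mM = stats::median(g$nh4_mM),
                 mean_d15N_permil = mean(g$d15N_nh4_permil),
                 mean_f_stream_air = mean(g$f_stream_air))
    }))
    rownames(summary_bins) <- NULL
  }

  counts <- list(
    water = list(n_input = nrow(water), n_analyzed = nrow(w),
                 n_skipped = nrow(w_skip)),
    droplets = list(n_input = drop_block$n_input,
                    n_analyzed = if (is.null(drop_block$analyzed)) 0L
                    else nrow(drop_block$analyzed),
                    n_skipped = nrow(drop_block$skipped)),
    air = list(n_input = air_block$n_input,
               n_analyzed = if (is.null(air_block$analyzed)) 0L
               else nrow(air_block$analyzed),
               n_skipped = nrow(air_block$skipped)))

  provenance <- list(
    seed = config$seed,
    config_hash = .md5_of(config[setdiff(names(config), "seed")]),
    input_hashes = list(water = .md5_of(water),
                        droplets = .md5_of(droplets),
                        air = .md5_of(air)))

  structure(list(schema_version = "1.0",
                 water = list(analyzed = w, skipped = w_skip),
                 droplets = drop_block[c("analyzed", "skipped")],
                 air = air_block[c("analyzed", "skipped")],
                 endmember_fit = emfit,
                 thermo = thermo,
                 summary = summary_bins,
                 counts = counts,
                 provenance = provenance),
            class = "nhx_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nhx_report <- function(x, ...) {
  cat("<nhx_report> schema", x$schema_version, "\n")
  w <- x$water$analyzed
  cat(sprintf("  streams: %d analyzed, %d skipped; NH3(g) %.2g-%.2g ppbv\n",
              x$counts$water$n_analyzed, x$counts$water$n_skipped,
              min(w$nh3_ppbv), max(w$nh3_ppbv)))
  if (!is.null(w$d15N_trapped_permil)) {
    cat(sprintf("  predicted trapped d15N: %.1f to %.1f permil\n",
                min(w$d15N_trapped_permil), max(w$d15N_trapped_permil)))
  }
  if (x$counts$droplets$n_input > 0) {
    cat(sprintf("  droplets: %d analyzed, %d skipped, %d out-of-hull\n",
                x$counts$droplets$n_analyzed, x$counts$droplets$n_skipped,
                sum(!x$droplets$analyzed$in_hull)))
  }
  if (x$counts$air$n_input > 0) {
    cat(sprintf("  air: %d analyzed, %d skipped\n",
                x$counts$air$n_analyzed, x$counts$air$n_skipped))
  }
  if (!is.null(x$endmember_fit)) {
    cat(sprintf(
      "  endmember fit: stream-air %.1f, surface %.1f permil (L = %.1f m)\n",
      x$endmember_fit$delta_stream_air, x$endmember_fit$delta_surface,
      x$endmember_fit$mixing_length_m))
  }
  for (nm in names(x$thermo)) {
    cat(sprintf("  dG to %s: %.0f%% of grid favorable, min %.1f kJ/mol\n",
                nm, 100 * x$thermo[[nm]]$frac_favorable,
                x$thermo[[nm]]$min_kJ_mol))
  }
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' Serializes an `nhx_report` (grids as row-major matrices with their axis
#' values preserved in dimnames) to a versioned JSON document.
#'
#' @param report an `nhx_report` from [run_analysis()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "nhx_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Run the built-in invariant suite
#'
#' Quick numerical self-checks of the model core: speciation limits and
#' monotonicity, Henry's-law round trip, linearity of the fractionation
#' chain, Rayleigh behaviour, mixing inversion, mass-balance
#' conservation, and thermodynamic path additivity. Intended for the
#' command line (`nhxiso selftest`) and smoke testing an installation.
#'
#' @param verbose print one line per check.
#' @return Invisibly, a data.frame with columns `check` and `pass`.
#' @export
selftest <- function(verbose = TRUE) {
  checks <- list(
    "speciation: frac_nh3 = 0.5 at the pKa" = function() {
      abs(speciate_nhx(10, 9.25, pKa = 9.25)$frac_nh3 - 0.5) < 1e-12
    },
    "speciation: fractions sum to 1" = function() {
      s <- speciate_nhx(123.4, 7.2, 13)
      abs(s$frac_nh3 + s$frac_nh4 - 1) < 1e-12
    },
    "speciation: monotone in pH" = function() {
      f <- speciate_nhx(10, seq(2, 12, 0.5), 25)$frac_nh3
      all(diff(f) > 0)
    },
    "henry: round trip recovers NH3(aq)" = function() {
      g <- equilibrium_nh3_gas(data.frame(pH = 7.2, temp_C = 13,
                                          nhx_uM = 100))
      abs(g$partial_pressure_atm * g$kh_M_per_atm - g$nh3_aq_M) <
        1e-10 * g$nh3_aq_M
    },
    "chain: linear total equals sum of eps" = function() {
      ch <- volatilization_chain(3.3, fractionation_set())
      abs((3.3 - ch$d15N_permil[5]) - 38.3) < 1e-12
    },
    "rayleigh: f = 1 returns delta0" = function() {
      rayleigh_remaining(3.3, 38.3, 1) == 3.3
    },
    "mixing: forward then invert recovers f" = function() {
      f <- 0.37
      d <- mix_deltas(f, -27.3, 15)
      abs(mixing_fraction(d, -27.3, 15)$f_A - f) < 1e-12
    },
    "mass balance: remixing recovers TDN" = function() {
      trn <- trn_mass_balance(2, 100, 8, 25)
      abs((trn * 75 + 8 * 25) / 100 - 2) < 1e-10
    },
    "thermo: nitrite + step = nitrate" = function() {
      cond <- thermo_conditions(pH = 2, nh4_total_M = 1e-3)
      g1 <- delta_g(reaction_ammonia_to_nitrite(), cond)
      g2 <- delta_g(reaction_nitrite_to_nitrate(), cond)
      g3 <- delta_g(reaction_ammonia_to_nitrate(), cond)
      abs(g1 + g2 - g3) < 1e-9 * abs(g3)
    })
  res <- data.frame(check = names(checks),
                    pass = vapply(checks, function(f) isTRUE(f()),
                                  logical(1)))
  if (verbose) {
    for (i in seq_len(nrow(res))) {
      cat(sprintf("[%s] %s\n", if (res$pass[i]) "ok" else "FAIL",
                  res$check[i]))
    }
    cat(sprintf("%d passed, %d failed\n", sum(res$pass), sum(!res$pass)))
  }
  invisible(res)
}
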