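#' @importFrom dplyr group_by summarise mutate filter bind_cols n_distinct
#' @importFrom utils write.csv read.csv
NULL

#' Desk-scale variant of the uncertain input space
#'
#' Same nine varied inputs and distribution families as
#' [parameter_space()], with the Reynolds and Womersley ranges re-centred
#' (+/-10% bands preserved) so that the resulting lattice Mach number
#' stays low on a small phantom. All other varied inputs keep their
#' published ranges.
#'
#' @param Re_centre,Wo_centre centre values of the desk-scale flow regime
#' @return a parameter-space tibble
#' @export
desk_parameter_space <- function(Re_centre = 10, Wo_centre = 6) {
  sp <- parameter_space()
  sp[sp$name == "Re", c("lower", "upper")] <-
    as.list(Re_centre * c(0.9, 1.1))
  sp[sp$name == "Wo", c("lower", "upper")] <-
    as.list(Wo_centre * c(0.9, 1.1))
  sp
}

#' Campaign configuration
#'
#' Bundles everything one uncertainty-quantification campaign needs: the
#' phantom geometry, the lattice constants, the uncertain input space, the
#' PCE degree and sample count, seeds, and the measurement protocol.
#'
#' @param phantom list describing the phantom: `kind` (`"branching"` or
#'   `"fusiform"`) plus the arguments of the corresponding builder
#' @param dx,dt lattice constants (m, s)
#' @param space uncertain input space; default [desk_parameter_space()]
#' @param p PCE degree
#' @param n_samples regression sample count; default `2 * basis_size(n, p)`
#' @param seed campaign seed
#' @param n_beats heartbeats after warm-up. With at least 4 beats the
#'   measurement window starts between the last four and three beats
#'   (phase fraction `T_s`) and lasts three; shorter runs measure over the
#'   last `min(3, n_beats)` beats and ignore the phase fraction
#' @param ref_outlet reference outlet index for the flow-ratio errors
#' @param sample_every traction/flow sampling stride (steps)
#' @param collect_fields also collect the per-wall-element TAWSS field for
#'   ensemble mean/CV maps
#' @param output_dir campaign output directory (created on demand)
#' @return an object of class `campaign_config`
#' @export
campaign_config <- function(phantom = list(kind = "branching",
                                           trunk_radius = 15e-4,
                                           outlet_radii = c(6e-4, 6.6e-4),
                                           length = 40e-4,
                                           bulge = list(amplitude = 4e-4,
                                                        halfwidth = 5e-4)),
                            dx = 1e-4, dt = 1.25e-4,
                            space = desk_parameter_space(),
                            p = 2, n_samples = NULL, seed = 1L,
                            n_beats = 4L, ref_outlet = 1L,
                            sample_every = 4L, collect_fields = FALSE,
                            output_dir = tempfile("campaign")) {
  n_var <- sum(space$dist != "constant")
  if (is.null(n_samples)) n_samples <- 2L * basis_size(n_var, p)
  if (n_samples < basis_size(n_var, p)) {
    abort("n_samples must be at least the PCE basis size",
          class = "hemouq_error_design")
  }
  stopifnot(n_beats >= 1)
  structure(list(phantom = phantom, dx = dx, dt = dt, space = space,
                 p = p, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), n_beats = as.integer(n_beats),
                 ref_outlet = as.integer(ref_outlet),
                 sample_every = as.integer(sample_every),
                 collect_fields = isTRUE(collect_fields),
                 output_dir = output_dir),
            class = "campaign_config")
}

build_phantom <- function(phantom, dx = NULL) {
  args <- phantom[setdiff(names(phantom), "kind")]
  if (is.null(args$dx)) args$dx <- dx
  switch(phantom$kind,
         branching = do.call(build_branching_phantom, args),
         fusiform = do.call(build_fusiform_phantom, args),
         abort(sprintf("unknown phantom kind '%s'", phantom$kind),
               class = "hemouq_error_config"))
}

# wall elements belonging to the aneurysm (bulge) region: within two
# half-widths of the bulge centre; all wall elements if there is no bulge
aneurysm_elements <- function(domain) {
  meta <- domain$meta
  z <- (domain$coords[domain$wall_sites, 3] - 0.5) * domain$dx
  if (identical(meta$kind, "fusiform") && (meta$bulge_amplitude %||% 0) > 0) {
    ctr <- meta$length / 2
    which(abs(z - ctr) < 2 * meta$bulge_halfwidth)
  } else if (identical(meta$kind, "branching")) {
    # the trunk wall (upstream of the split) hosts the bulge, if any
    which(z < meta$split_z)
  } else {
    seq_along(domain$wall_sites)
  }
}

#' Run one flow simulation for one parameter sample
#'
#' Maps a sampled parameter vector onto the solver configuration (magic
#' parameter, inlet Reynolds/Womersley numbers, elastic wall modulus and
#' velocity ratio, Murray exponent, Windkessel scalings, measurement
#' phase), executes warm-up plus `n_beats` heartbeats, and extracts the
#' scalar QoIs: aneurysm-wall averages of TAWSS, OSI, ECAP and RRT and the
#' per-outlet flow-ratio errors. Instability or a Mach number reaching 0.2
#' is reported as a failure record, never silently dropped.
#'
#' @param sample named list or one-row tibble with the varied inputs
#' @param config a [campaign_config()]
#' @param domain optional prebuilt phantom (rebuilt from the config when
#'   omitted)
#' @return one-row tibble of QoIs and run diagnostics
#' @export
run_single <- function(sample, config, domain = NULL) {
  sample <- as.list(sample)
  if (is.null(domain)) domain <- build_phantom(config$phantom, config$dx)
  # parameters held constant in this space take their fixed values
  for (k in seq_len(nrow(config$space))) {
    nm <- config$space$name[k]
    if (is.null(sample[[nm]])) sample[[nm]] <- config$space$lower[k]
  }
  consts <- config$space[config$space$dist == "constant", ]
  cval <- setNames(consts$lower, consts$name)
  spec <- lattice_spec(config$dx, config$dt,
                       rho_ref = cval[["rho"]], mu = cval[["mu"]],
                       Lambda = sample$Lambda)
  out <- tryCatch({
    prof <- inlet_from_numbers(sample$Re, sample$Wo,
                               rho = cval[["rho"]], mu = cval[["mu"]],
                               r_inlet = domain$inlet_plane$equivalent_radius,
                               n_beats = config$n_beats, spec = spec)
    wp <- wall_properties(E = sample$E, h = cval[["h"]],
                          r_hat = cval[["r_hat"]], F = sample$F,
                          sigma = cval[["sigma"]])
    radii <- vapply(domain$outlet_planes, `[[`, numeric(1),
                    "equivalent_radius")
    phi <- murray_fractions(radii, m = sample$m,
                            ref_index = config$ref_outlet)
    wk <- windkessel_parameters(phi, prof$omega0, sample$gamma_R,
                                sample$gamma_C,
                                Z0 = characteristic_impedance(spec, domain))
    t_f <- prof$warmup + config$n_beats * prof$T0
    win <- if (config$n_beats >= 4) {
      measurement_window(t_f, prof$T0, u = sample$T_s)
    } else {
      nb <- min(3, config$n_beats)
      list(T_s = t_f - nb * prof$T0, T_f = t_f)
    }
    st <- run_simulation(domain, spec, inlet = prof, wall_props = wp,
                         wk = wk, q_smooth_steps = 1,
                         measure = list(start = win$T_s, end = win$T_f,
                                        sample_every = config$sample_every),
                         collect_wss = TRUE)
    if (!st$valid) {
      abort(sprintf("maximum Mach number %.3f reached 0.2", st$ma_max),
            class = "hemouq_error_mach")
    }
    fld <- risk_factor_field(st$wss_series)
    an <- aneurysm_elements(domain)
    wall_mean <- function(x) mean(x[is.finite(x)])
    qm <- summarise(group_by(st$outlet_series, .data$outlet_index),
                    q = mean(.data$Q_m3s))
    errs <- q_ratio_errors(qm$q, phi, config$ref_outlet)
    rec <- tibble(
      status = "ok", reason = NA_character_,
      tawss = wall_mean(fld$tawss[an]), osi = wall_mean(fld$osi[an]),
      ecap = wall_mean(fld$ecap[an]), rrt = wall_mean(fld$rrt[an]),
      ma_max = st$ma_max
    )
    for (k in seq_len(nrow(errs))) {
      rec[[paste0("q_err_", errs$outlet[k])]] <- errs$rel_error[k]
    }
    if (config$collect_fields) {
      attr(rec, "tawss_field") <- fld$tawss
    }
    rec
  }, hemouq_error_instability = function(e) {
    tibble(status = "failed", reason = conditionMessage(e),
           tawss = NA_real_, osi = NA_real_, ecap = NA_real_,
           rrt = NA_real_, ma_max = NA_real_)
  }, hemouq_error_mach = function(e) {
    tibble(status = "failed", reason = conditionMessage(e),
           tawss = NA_real_, osi = NA_real_, ecap = NA_real_,
           rrt = NA_real_, ma_max = NA_real_)
  })
  out
}

#' Run a full uncertainty-quantification campaign
#'
#' Draws the seeded sample design, evaluates the flow model (or a supplied
#' mock) for every sample, fits one regression PCE per scalar QoI, and
#' derives moments, coefficients of variation, CVRs and Sobol' indices.
#' Per-sample results are appended to `samples.csv` in the output
#' directory as they complete; with `resume = TRUE` finished samples are
#' not re-run. Failed samples are kept in the ledger and excluded from the
#' regression (with a warning when they exceed 5% of the design).
#'
#' @param config a [campaign_config()]
#' @param model optional mock: a `function(sample)` returning a named list
#'   of QoIs, replacing the flow solver (used for pipeline validation)
#' @param resume reuse finished samples found in the output directory
#' @return an object of class `campaign_result`
#' @export
run_campaign <- function(config, model = NULL, resume = FALSE) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  X <- draw_samples(config$space, config$n_samples, config$seed)
  domain <- if (is.null(model)) build_phantom(config$phantom, config$dx)
  samples_file <- file.path(config$output_dir, "samples.csv")
  done <- NULL
  if (resume && file.exists(samples_file)) {
    done <- as_tibble(read.csv(samples_file))
  }
  rows <- list()
  fields <- list()
  for (i in seq_len(config$n_samples)) {
    if (!is.null(done) && i %in% done$sample) {
      rows[[i]] <- done[done$sample == i, , drop = FALSE]
      next
    }
    smp <- X[i, ]
    rec <- if (is.null(model)) {
      run_single(smp, config, domain = domain)
    } else {
      as_tibble(c(list(status = "ok", reason = NA_character_),
                  model(smp), list(ma_max = 0)))
    }
    if (!is.null(attr(rec, "tawss_field"))) {
      fields[[i]] <- attr(rec, "tawss_field")
      attr(rec, "tawss_field") <- NULL
    }
    rec <- bind_cols(tibble(sample = i), smp, rec)
    rows[[i]] <- rec
    all_rows <- dplyr::bind_rows(rows)
    write.csv(all_rows, samples_file, row.names = FALSE)
  }
  results <- dplyr::bind_rows(rows)
  ok <- results$status == "ok"
  if (mean(!ok) > 0.05) {
    warning(sprintf("%.1f%% of samples failed; regression uses %d of %d",
                    100 * mean(!ok), sum(ok), length(ok)))
  }
  qoi_cols <- setdiff(names(results),
                      c("sample", varied_rows(config$space)$name,
                        "status", "reason", "ma_max"))
  Y <- as.matrix(results[ok, qoi_cols, drop = FALSE])
  keep <- colSums(!is.finite(Y)) == 0
  Y <- Y[, keep, drop = FALSE]
  pce <- fit_pce(results[ok, varied_rows(config$space)$name], Y,
                 p = config$p, space = config$space)
  mom <- pce_moments(pce)
  aic <- average_input_cv(config$space)
  mom$cv <- sqrt(mom$variance) / abs(mom$mean)
  mom$cvr <- mom$cv / aic
  sob <- sobol_from_pce(pce)
  field_stats <- NULL
  if (length(fields)) {
    fm <- do.call(rbind, fields[ok[seq_along(fields)] &
                                  !vapply(fields, is.null, logical(1))])
    field_stats <- tibble(element = seq_len(ncol(fm)),
                          mean = colMeans(fm),
                          cv = apply(fm, 2, stats::sd) / colMeans(fm))
  }
  res <- structure(list(
    config = config, samples = results, pce = pce, moments = mom,
    input_cvs = input_cvs(config$space), average_input_cv = aic,
    sobol = sob, field_stats = field_stats, domain = domain
  ), class = "campaign_result")
  report(res)
  res
}

#' Write the campaign report files
#'
#' Emits the summary tables: per-input CVs with their average, per-QoI
#' moments/CV/CVR, first/total Sobol' indices, second-order interaction
#' indices, run metadata, and (when wall fields were collected) VTK maps
#' of the ensemble mean and CV of TAWSS over the wall elements.
#'
#' @param result a `campaign_result`
#' @param dir output directory; defaults to the campaign's
#' @return the directory, invisibly
#' @export
report <- function(result, dir = result$config$output_dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  ic <- result$input_cvs
  ic <- dplyr::bind_rows(ic, tibble(name = "average",
                                    cv = result$average_input_cv))
  write.csv(ic, file.path(dir, "input_cvs.csv"), row.names = FALSE)
  write.csv(result$moments, file.path(dir, "qoi_stats.csv"),
            row.names = FALSE)
  first <- as_tibble(result$sobol$first, rownames = "input")
  total <- as_tibble(result$sobol$total, rownames = "input")
  write.csv(first, file.path(dir, "sobol_first.csv"), row.names = FALSE)
  write.csv(total, file.path(dir, "sobol_total.csv"), row.names = FALSE)
  write.csv(result$sobol$second, file.path(dir, "sobol_second.csv"),
            row.names = FALSE)
  meta <- list(seed = cfg$seed, p = cfg$p, Np = result$pce$basis_size,
               n_samples = cfg$n_samples,
               n_completed = sum(result$samples$status == "ok"),
               n_failed = sum(result$samples$status != "ok"),
               condition = result$pce$condition)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$field_stats) && !is.null(result$domain)) {
    export_vtk(result$domain, file.path(dir, "tawss_mean.vtk"),
               field = result$field_stats$mean, name = "tawss_mean")
    export_vtk(result$domain, file.path(dir, "tawss_cv.vtk"),
               field = result$field_stats$cv, name = "tawss_cv")
  }
  invisible(dir)
}

#' @export
print.campaign_result <- function(x, ...) {
  cat(sprintf("<campaign_result> p = %d, %d/%d samples completed\n",
              x$config$p, sum(x$samples$status == "ok"),
              nrow(x$samples)))
  print(x$moments)
  invisible(x)
}
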