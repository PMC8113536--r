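# File schemas, configuration, and the pipeline driver chaining
# simulate -> preprocess -> select -> associate. All interchange files are
# tab-delimited text with fixed headers; missing values are empty fields.

read_table_checked <- function(path, required, numeric_cols) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                   colClasses = "character")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- rep(FALSE, nrow(df))
  for (cl in numeric_cols) {
    raw <- df[[cl]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- bad | (!is.na(raw) & is.na(num))
    df[[cl]] <- num
  }
  if (any(bad)) {
    warning(sprintf("rejected %d row(s) with unparseable numerics at line(s): %s",
                    sum(bad),
                    paste(which(bad) + 1L, collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  attr(df, "n_rejected") <- sum(bad)
  df
}

#' Read a survey response table
#'
#' Tab-delimited text with header `species, response, lon, lat, year,
#' value`. Rows with unparseable numerics are rejected with their line
#' numbers; empty value fields become missing flags and are counted.
#'
#' @param path file path.
#' @return data frame of typed records with attributes `n_rejected` and
#'   `n_missing_value`.
#' @export
read_survey_table <- function(path) {
  df <- read_table_checked(path,
                           required = c("species", "response", "lon", "lat",
                                        "year", "value"),
                           numeric_cols = c("lon", "lat", "year", "value"))
  df$year <- as.integer(df$year)
  attr(df, "n_missing_value") <- sum(is.na(df$value))
  df
}

#' Read a monthly environmental station table
#'
#' Header `variable, lon, lat, year, month, value`; months outside 1..12
#' are rejected; duplicate (variable, location, year, month) rows resolve
#' last-wins with a warning.
#'
#' @param path file path.
#' @return typed data frame.
#' @export
read_env_table <- function(path) {
  df <- read_table_checked(path,
                           required = c("variable", "lon", "lat", "year",
                                        "month", "value"),
                           numeric_cols = c("lon", "lat", "year", "month",
                                            "value"))
  df$year <- as.integer(df$year)
  df$month <- as.integer(df$month)
  bad_month <- !is.na(df$month) & (df$month < 1 | df$month > 12)
  if (any(bad_month)) {
    warning(sprintf("rejected %d row(s) with month outside 1..12",
                    sum(bad_month)))
    df <- df[!bad_month, , drop = FALSE]
  }
  key <- paste(df$variable, loc_key(df$lon, df$lat), df$year, df$month)
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    warning(sprintf("%d duplicate (variable, location, year, month) row(s): last wins",
                    sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  df
}

#' Read a monthly climate-index table
#'
#' Header `index, year, month, value`; months outside 1..12 rejected,
#' duplicates last-wins.
#'
#' @param path file path.
#' @return typed data frame.
#' @export
read_climate_table <- function(path) {
  df <- read_table_checked(path,
                           required = c("index", "year", "month", "value"),
                           numeric_cols = c("year", "month", "value"))
  df$year <- as.integer(df$year)
  df$month <- as.integer(df$month)
  bad_month <- !is.na(df$month) & (df$month < 1 | df$month > 12)
  if (any(bad_month)) {
    warning(sprintf("rejected %d row(s) with month outside 1..12",
                    sum(bad_month)))
    df <- df[!bad_month, , drop = FALSE]
  }
  key <- paste(df$index, df$year, df$month)
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    warning(sprintf("%d duplicate (index, year, month) row(s): last wins",
                    sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline: the per-species lag map (10
#' years for Pacific halibut, 5 for all other species), the VIF threshold
#' of 5, the inverse-distance power of 2, the eight-interior-knot cubic
#' spline basis, the penalty-path spec, the winter-window convention, the
#' FDR family mode, and the seeds.
#'
#' @param species_lags named numeric vector of explicit per-species lag
#'   overrides; every species named here must appear in the survey file.
#' @param default_lag lag for species without an override (default 5;
#'   Pacific halibut responses default to 10 via `halibut_lag`).
#' @param halibut_lag lag applied to species whose name contains
#'   "halibut" (default 10, reflecting their later sexual maturity).
#' @param vif_threshold VIF elimination threshold (default 5).
#' @param idw_power inverse-distance power (default 2).
#' @param djf_year_convention `"previous"` or `"same"`.
#' @param fdr_family `"pooled"` or `"per_index"`.
#' @param years_window screening window (default 1985:2013).
#' @param seed integer master seed.
#' @param control a [sivcm_control()] list for the estimator.
#' @param sim simulation settings for the `simulate` stage (list; see
#'   [simulate_study()]).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(species_lags = c(),
                            default_lag = 5,
                            halibut_lag = 10,
                            vif_threshold = 5,
                            idw_power = 2,
                            djf_year_convention = "previous",
                            fdr_family = "pooled",
                            years_window = 1985:2013,
                            seed = 1L,
                            control = sivcm_control(),
                            sim = list()) {
  stopifnot(vif_threshold > 0, idw_power > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

species_lag <- function(config, species) {
  if (species %in% names(config$species_lags)) {
    unname(config$species_lags[species])
  } else if (grepl("halibut", species, ignore.case = TRUE)) {
    config$halibut_lag
  } else {
    config$default_lag
  }
}

#' Simulate a complete synthetic study to disk
#'
#' Generates coherent survey, environment and climate files with a truth
#' sidecar: station series with location-year-varying seasonal amplitudes,
#' survey responses built from the true SIVCM on the (lagged) amplitudes
#' the preprocessing stage will reconstruct, and monthly climate indices.
#'
#' @param config a [pipeline_config()]; `config$sim` may override
#'   `n_per_year`, `years`, `p_env`, `species`, `response`, `snr`,
#'   `env_noise_sd`.
#' @param out_dir output directory.
#' @return invisible list of written file paths.
#' @export
simulate_study <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim
  n_per_year <- sim$n_per_year %||% 20L
  years <- sim$years %||% config$years_window
  p_env <- sim$p_env %||% 10L
  species <- sim$species %||% "sablefish"
  response <- sim$response %||% "CPUE"
  snr <- sim$snr %||% 5
  env_noise_sd <- sim$env_noise_sd %||% 0.05
  lag <- species_lag(config, species)
  seed <- as.integer(config$seed)
  conv <- config$djf_year_convention

  set.seed(seed)
  # station grid and survey points in a Gulf-of-Alaska-like box
  stations <- expand.grid(lon = seq(-168, -132, length.out = 4),
                          lat = seq(52, 60, length.out = 3))
  amp_years <- sort(unique(c(years - lag, years)))
  vars <- paste0("env", seq_len(p_env))
  classes <- setNames(rep(c("physical", "chembio"), length.out = p_env), vars)
  # per (variable, station, year) configured amplitudes: smooth in space,
  # noisy across years
  spec_vars <- list()
  env_rows <- list()
  for (j in seq_len(p_env)) {
    sm <- season_months(classes[j])
    for (si in seq_len(nrow(stations))) {
      a <- 1 + 0.02 * (stations$lon[si] + 150) + 0.05 * (stations$lat[si] - 56) +
        rnorm(length(amp_years), sd = 0.5) + 0.3 * sin(2 * pi * seq_along(amp_years) / 8)
      for (k in seq_along(amp_years)) {
        mm <- rep(0, 12)
        mm[sm$high] <- a[k] / 2
        mm[sm$low] <- -a[k] / 2
        yrs_assign <- rep(amp_years[k], 12)
        if (classes[j] == "physical" && conv == "previous") {
          yrs_assign[12] <- amp_years[k] - 1L
        }
        env_rows[[length(env_rows) + 1L]] <- data.frame(
          variable = vars[j], lon = stations$lon[si], lat = stations$lat[si],
          year = yrs_assign, month = 1:12,
          value = mm + rnorm(12, sd = env_noise_sd))
      }
    }
  }
  env_table <- do.call(rbind, env_rows)

  # survey locations, one set per year
  survey <- do.call(rbind, lapply(years, function(yr) {
    data.frame(species = species, response = response,
               lon = runif(n_per_year, -166, -134),
               lat = runif(n_per_year, 53, 59),
               year = yr, value = NA_real_)
  }))

  # reconstruct the lagged amplitude design exactly as preprocessing will
  pts <- unique(survey[, c("lon", "lat")])
  amp_tab <- build_amplitude_table(env_table, pts, classes,
                                   power = config$idw_power,
                                   djf_year_convention = conv)
  design0 <- lag_align(amp_tab, transform(survey, value = 0), lag)
  # truth: index over (lon, lat, year), three signal-bearing variables
  truth <- sivcm_truth(p = p_env,
                       nonzero = sim$nonzero %||% seq_len(min(3, p_env)),
                       n = nrow(design0$X), snr = snr, seed = seed)
  Zs <- scale(design0$Z)
  u <- drop(Zs %*% truth$theta_true)
  Xs <- scale(design0$X[, -1, drop = FALSE])
  G <- vapply(truth$g_funcs, function(g) g(u), numeric(length(u)))
  signal <- G[, 1] + rowSums(G[, -1, drop = FALSE] * Xs)
  noise_sd <- sd(signal) / sqrt(snr)
  yv <- signal + rnorm(length(signal), sd = noise_sd)
  # place the responses back on the survey rows that survived alignment
  key_design <- paste(loc_key(design0$Z[, "lon"], design0$Z[, "lat"]),
                      design0$Z[, "year"])
  key_survey <- paste(loc_key(survey$lon, survey$lat), survey$year)
  survey$value <- yv[match(key_survey, key_design)]

  clim_years <- sort(unique(c(config$years_window - max(10, lag),
                              config$years_window)))
  amp_params <- list(
    PDO = setNames(1.2 * sin(2 * pi * seq_along(clim_years) / 20) +
                     rnorm(length(clim_years), sd = 0.3), clim_years),
    MEI = setNames(0.8 * cos(2 * pi * seq_along(clim_years) / 7) +
                     rnorm(length(clim_years), sd = 0.3), clim_years),
    NPGO = setNames(rnorm(length(clim_years), sd = 1), clim_years))
  climate <- gen_climate_indices(clim_years, amp_params, noise_sd = 0.02,
                                 seed = seed + 1L, djf_convention = conv)

  paths <- list(survey = file.path(out_dir, "survey.tsv"),
                env = file.path(out_dir, "env.tsv"),
                climate = file.path(out_dir, "climate.tsv"),
                truth = file.path(out_dir, "truth.json"))
  write_tsv(survey, paths$survey)
  write_tsv(env_table, paths$env)
  write_tsv(climate, paths$climate)
  jsonlite::write_json(
    list(theta_true = truth$theta_true, nonzero = truth$nonzero,
         nonzero_vars = colnames(design0$X)[-1][truth$nonzero],
         p = truth$p, snr = snr, noise_sd = noise_sd, lag = lag,
         classes = as.list(classes), seed = seed),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

stage_manifest <- function(out_dir, stage, inputs, counts, config) {
  cfg_txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  manifest <- list(stage = stage, inputs = inputs, counts = counts,
                   seed = config$seed,
                   config_hash = unname(tools::md5sum(
                     {f <- tempfile(); writeLines(cfg_txt, f); f})))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the pipeline end to end
#'
#' Executes the configured stages in order — `simulate` (synthetic study
#' files), `preprocess` (interpolated amplitudes, VIF pruning, lag-aligned
#' design), `select` (per-year and all-years selection matrix), and
#' `associate` (logistic screening and the additive climate model) — each
#' writing its outputs and a provenance manifest under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param stages subset of stages to run, in order.
#' @return invisible list of stage outputs (paths and in-memory objects).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "preprocess", "select",
                                    "associate")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  if ("simulate" %in% stages) {
    res$simulate <- simulate_study(config, out_dir)
    stage_manifest(out_dir, "simulate", character(0),
                   list(files = length(res$simulate)), config)
  }
  survey <- read_survey_table(file.path(out_dir, "survey.tsv"))
  unknown <- setdiff(names(config$species_lags), unique(survey$species))
  if (length(unknown)) {
    stop("lag map names species not present in the survey file: ",
         paste(unknown, collapse = ", "))
  }
  if ("preprocess" %in% stages) {
    env <- read_env_table(file.path(out_dir, "env.tsv"))
    truth <- jsonlite::read_json(file.path(out_dir, "truth.json"),
                                 simplifyVector = TRUE)
    classes <- unlist(truth$classes)
    pts <- unique(survey[, c("lon", "lat")])
    amp_tab <- build_amplitude_table(env, pts, classes,
                                     power = config$idw_power,
                                     djf_year_convention = config$djf_year_convention)
    write_tsv(amp_tab, file.path(out_dir, "amplitudes.tsv"))
    designs <- list()
    for (sp in unique(survey$species)) {
      for (rp in unique(survey$response[survey$species == sp])) {
        sub <- survey[survey$species == sp & survey$response == rp, ]
        d <- lag_align(amp_tab, sub, species_lag(config, sp))
        # collinearity pruning on the candidate variables
        vrep <- vif_backward_eliminate(d$X[, -1, drop = FALSE],
                                       threshold = config$vif_threshold)
        keep <- c("(Intercept)", vrep$retained)
        d$X <- d$X[, keep, drop = FALSE]
        d$vif_report <- vrep
        designs[[paste(sp, rp, sep = "_")]] <- d
      }
    }
    res$preprocess <- list(amplitudes = amp_tab, designs = designs)
    saveRDS_ascii(designs, file.path(out_dir, "designs.txt"))
    stage_manifest(out_dir, "preprocess",
                   c("survey.tsv", "env.tsv"),
                   list(amplitude_rows = nrow(amp_tab),
                        designs = length(designs),
                        dropped = vapply(designs, function(d) d$n_dropped,
                                         numeric(1))),
                   config)
  }
  if ("select" %in% stages) {
    designs <- res$preprocess$designs %||%
      readRDS_ascii(file.path(out_dir, "designs.txt"))
    sels <- list()
    for (nm in names(designs)) {
      sm <- run_yearly_selection(designs[[nm]], control = config$control)
      selection_matrix_to_table(sm, file.path(out_dir,
                                              paste0("selection_", nm, ".tsv")))
      sels[[nm]] <- sm
    }
    res$select <- sels
    stage_manifest(out_dir, "select", "designs",
                   list(matrices = length(sels)), config)
  }
  if ("associate" %in% stages) {
    sels <- res$select
    if (is.null(sels)) {
      # standalone invocation: rebuild the matrices from the select stage's
      # files (name pattern selection_<species>_<response>.tsv)
      files <- list.files(out_dir, pattern = "^selection_.*\\.tsv$")
      if (!length(files)) stop("associate stage requires select stage outputs")
      sels <- list()
      for (f in files) {
        nm <- sub("^selection_", "", sub("\\.tsv$", "", f))
        parts <- strsplit(nm, "_")[[1]]
        m <- read_selection_table(file.path(out_dir, f))
        sels[[nm]] <- structure(m,
                                species = paste(head(parts, -1), collapse = "_"),
                                response = parts[length(parts)],
                                class = c("selection_matrix", "matrix"))
      }
    }
    climate <- read_climate_table(file.path(out_dir, "climate.tsv"))
    assoc <- list(); gams <- list()
    for (nm in names(sels)) {
      sp <- attr(sels[[nm]], "species")
      lag <- species_lag(config, sp)
      a <- associate_selection(sels[[nm]], climate, lag = lag,
                               years_window = config$years_window,
                               djf_convention = config$djf_year_convention,
                               family_mode = config$fdr_family)
      write_tsv(as.data.frame(a), file.path(out_dir,
                                            paste0("association_", nm, ".tsv")))
      assoc[[nm]] <- a
      # yearly mean response for the additive climate model; only the PDO
      # amplitude is lagged, per the model specification
      sub <- survey[survey$species == sp, ]
      ymean <- tapply(sub$value, sub$year, mean, na.rm = TRUE)
      yrs <- intersect(as.integer(names(ymean)), config$years_window)
      amp <- climate_amplitude_table(climate, yrs,
                                     lags = c(PDO = lag, MEI = 0, NPGO = 0),
                                     djf_convention = config$djf_year_convention)
      g <- tryCatch(fit_additive_model(as.numeric(ymean[as.character(yrs)]),
                                       amp),
                    error = function(e) NULL)
      if (!is.null(g)) {
        gams[[nm]] <- data.frame(model = nm,
                                 smooth = names(g$p),
                                 edf = as.numeric(g$edf),
                                 p = as.numeric(g$p),
                                 deviance_explained = g$deviance_explained)
      }
    }
    if (length(gams)) {
      write_tsv(do.call(rbind, gams), file.path(out_dir, "gam_summaries.tsv"))
    }
    res$associate <- list(associations = assoc, gams = gams)
    stage_manifest(out_dir, "associate", "selection matrices",
                   list(tables = length(assoc)), config)
  }
  invisible(res)
}

# plain-text serialization for intermediate designs (deliverables are text
# only; dput round-trips numeric vectors exactly via full precision)
saveRDS_ascii <- function(obj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  dput(obj, file = con, control = c("all", "hexNumeric"))
  invisible(path)
}

readRDS_ascii <- function(path) {
  dget(path)
}
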