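#' @useDynLib tetherscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

pkg_version <- function() {
  as.character(utils::packageVersion("tetherscope"))
}

# Rolling-polynomial fingerprint (mod 2^31 - 1) of a deparsed object; used
# to stamp output files with the configuration they came from.
config_fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ";"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance_header <- function(seed = NULL, config = NULL, units = "b",
                              time_unit = "b^2/D") {
  c(sprintf("# tetherscope %s", pkg_version()),
    sprintf("# units: %s time_unit: %s", units, time_unit),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else seed),
    sprintf("# config: %s", config_fingerprint(config)))
}

#' Read a single-locus trajectory from CSV
#'
#' Expects a header `time,x,y[,z]` (comment lines starting with `#` are
#' skipped, and a `# units:` comment, as written by [write_locus_csv()], is
#' honoured). The time column is authoritative: the frame interval is
#' inferred from it and must be uniform to within a relative tolerance of
#' 1e-6. Malformed rows -- non-numeric or missing coordinates, non-monotone
#' time -- raise errors naming the offending data line.
#'
#' @param path CSV file path.
#' @param units,time_unit unit declarations used when the file carries none.
#' @param label identifier; default the file name without extension.
#' @return A [locus_trajectory()].
#' @export
read_locus_csv <- function(path, units = NULL, time_unit = NULL,
                           label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- readLines(path, n = 20L)
  uline <- grep("^# units:", hdr, value = TRUE)
  if (length(uline)) {
    m <- regmatches(uline[1L],
                    regexec("^# units: (\\S+) time_unit: (\\S+)", uline[1L]))[[1L]]
    if (length(m) == 3L) {
      if (is.null(units)) units <- m[2L]
      if (is.null(time_unit)) time_unit <- m[3L]
    }
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  cols <- tolower(names(df))
  if (cols[1L] != "time" || ncol(df) < 3L || ncol(df) > 4L ||
      !all(cols[-1L] %in% c("x", "y", "z")))
    stop("expected columns time,x,y[,z]; got: ",
         paste(names(df), collapse = ","), call. = FALSE)
  mat <- matrix(suppressWarnings(as.numeric(as.matrix(df))), nrow(df))
  bad <- which(rowSums(!is.finite(mat)) > 0)
  if (length(bad))
    stop(sprintf("non-finite or missing values at data row(s) %s of %s",
                 paste(utils::head(bad, 5L), collapse = ", "), path),
         call. = FALSE)
  df <- as.data.frame(mat)
  names(df) <- cols
  tm <- df[[1L]]
  if (any(diff(tm) <= 0))
    stop(sprintf("non-monotone time at data row %d of %s",
                 which(diff(tm) <= 0)[1L] + 1L, path), call. = FALSE)
  dts <- diff(tm)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * max(abs(dt), 1e-300)))
    stop(sprintf("frame interval not uniform (max deviation %.3g vs dt %.3g) in %s",
                 max(abs(dts - dt)), dt, path), call. = FALSE)
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  locus_trajectory(as.matrix(df[, -1L, drop = FALSE]), dt = dt,
                   units = units %||% "b", time_unit = time_unit %||% "b^2/D",
                   label = label)
}

#' Write a single-locus trajectory to CSV
#'
#' One row per frame, columns `time,x,y[,z]`, preceded by `#` comment lines
#' recording the package version, units, seed and a configuration
#' fingerprint. [read_locus_csv()] round-trips such files at full double
#' precision.
#'
#' @param traj a [locus_trajectory()].
#' @param path output path.
#' @param seed,config optional provenance to embed in the header.
#' @return `path`, invisibly.
#' @export
write_locus_csv <- function(traj, path, seed = NULL, config = NULL) {
  stopifnot(inherits(traj, "locus_trajectory"))
  P <- traj$positions
  df <- data.frame(time = seq_len(nrow(P)) * traj$dt)
  for (j in seq_len(ncol(P))) df[[colnames(P)[j]]] <- P[, j]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config, traj$units, traj$time_unit), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a full-chain trajectory to CSV
#'
#' One row per frame: `time`, then `x,y[,z]` per recorded monomer in chain
#' order, columns named `m<index>_x` etc.
#'
#' @param traj a `polymer_trajectory` from [simulate_polymer()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "polymer_trajectory"))
  pos <- traj$positions
  nf <- dim(pos)[1L]; nm <- dim(pos)[2L]; d <- dim(pos)[3L]
  df <- data.frame(time = seq_len(nf) * traj$dt)
  for (i in seq_len(nm))
    for (j in seq_len(d))
      df[[sprintf("m%s_%s", dimnames(pos)[[2L]][i], c("x", "y", "z")[j])]] <-
        pos[, i, j]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(traj$seed, traj$config), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation configuration file
#'
#' YAML (or JSON) with keys `polymer` (`N`, `beta`, `kappa`, `b`, `D`, `d`),
#' `wells` (list of `{n, k, mu}`) and `sim` (`dt`, `n_steps`, `burn_in`,
#' `seed`, `record_every`, `init`).
#'
#' @param path config file path.
#' @return A list with elements `spec` ([polymer_spec()]), `wells` (list of
#'   [well_spec()]) and `config` ([sim_config()]).
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$polymer)) stop("config lacks a `polymer` block", call. = FALSE)
  p <- cfg$polymer
  # YAML 1.1 parses bare N/n/y keys as booleans; accept both spellings
  spec <- polymer_spec(N = p$N %||% p[["FALSE"]],
                       beta = p$beta %||% 2, kappa = p$kappa %||% 3,
                       b = p$b %||% 1, D = p$D %||% 1, d = p$d %||% 3)
  wells <- lapply(cfg$wells %||% list(), function(w)
    well_spec(n = w$n %||% w[["FALSE"]], k = w$k,
              mu = unlist(w$mu) %||% rep(0, spec$d)))
  s <- cfg$sim %||% list()
  config <- sim_config(dt = s$dt %||% 0.01, n_steps = s$n_steps %||% 10000L,
                       burn_in = s$burn_in, seed = s$seed,
                       record_every = s$record_every %||% 1L,
                       init = s$init %||% "well-centered")
  list(spec = spec, wells = wells, config = config)
}

#' Generate a synthetic fixture with known ground truth
#'
#' Produces locus trajectory CSV files together with a JSON sidecar holding
#' every generating parameter and the analytic effective stiffness each
#' trajectory should yield. Scenarios:
#' \describe{
#'   \item{`"ou"`}{single particle in a well (`k = 2`, `D = 1`, `d = 3`).}
#'   \item{`"tethered-rouse"`}{`N = 30` Rouse chain, first monomer tethered
#'     (`k = 2`, `kappa = 3`, `dt = 0.01`), loci recorded at the tethered
#'     (1), middle (16) and end (30) monomers -- analytic stiffnesses
#'     2, 6/33 and 6/61.}
#'   \item{`"tethered-beta"`}{as above with `beta = 1.5`; truth from
#'     [effective_stiffness_beta()].}
#'   \item{`"two-well"`}{`N = 21` chain with both ends tethered (wells at
#'     the origin and `(5, 0, 0)`), middle monomer recorded; truth from
#'     [effective_stiffness_two_wells()] and [mean_position_two_wells()].}
#'   \item{`"free-chain"`}{free `N = 30` Rouse chain, middle monomer.}
#' }
#' Output is deterministic for a fixed `seed`.
#'
#' @param scenario one of the scenario names above.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_steps recorded frames per trajectory.
#' @param ... overrides passed to the scenario (e.g. `k`, `kappa`, `N`).
#' @return Invisibly, a list with `files` (CSV paths), `truth_file`, and the
#'   `truth` list itself.
#' @export
generate_fixture <- function(scenario = c("tethered-rouse", "ou",
                                          "tethered-beta", "two-well",
                                          "free-chain"),
                             dir, seed = 1L, n_steps = 20000L, ...) {
  scenario <- match.arg(scenario)
  dots <- list(...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  get <- function(name, default) dots[[name]] %||% default
  files <- character(0)
  truth <- list(scenario = scenario, seed = seed,
                package_version = pkg_version())

  if (scenario == "ou") {
    k <- get("k", 2); D <- get("D", 1); d <- get("d", 3)
    dt <- get("dt", 0.01)
    tr <- simulate_ou(k = k, D = D, d = d, dt = dt, n_steps = n_steps,
                      seed = seed)
    f <- file.path(dir, "ou_locus.csv")
    write_locus_csv(tr, f, seed = seed, config = truth)
    files <- f
    truth$params <- list(k = k, D = D, d = d, dt = dt, n_steps = n_steps)
    truth$k_c <- k
    truth$variance_per_axis <- 1 / k
  } else if (scenario %in% c("tethered-rouse", "tethered-beta")) {
    beta <- if (scenario == "tethered-beta") get("beta", 1.5) else 2
    N <- get("N", 30L); kappa <- get("kappa", 3); k <- get("k", 2)
    n <- get("n", 1L); dt <- get("dt", 0.01)
    tagged <- get("tagged", c(1L, (N %/% 2L) + 1L, N))
    spec <- polymer_spec(N = N, beta = beta, kappa = kappa, D = get("D", 1),
                         d = get("d", 3))
    well <- well_spec(n = n, k = k, mu = rep(0, spec$d))
    tr <- simulate_polymer(spec, list(well),
                           sim_config(dt = dt, n_steps = n_steps, seed = seed),
                           tagged = tagged)
    k_c <- vapply(tagged, function(cc)
      effective_stiffness_beta(spec, well, cc)$value, 0)
    files <- vapply(seq_along(tagged), function(i) {
      f <- file.path(dir, sprintf("%s_m%02d.csv", scenario, tagged[i]))
      write_locus_csv(tagged_locus(tr, tagged[i]), f, seed = seed,
                      config = truth)
      f
    }, "")
    truth$params <- list(N = N, beta = beta, kappa = kappa, k = k, n = n,
                         dt = dt, n_steps = n_steps, D = spec$D, d = spec$d,
                         tagged = tagged)
    truth$k_c <- as.list(stats::setNames(k_c, paste0("monomer", tagged)))
    truth$variance <- as.list(stats::setNames(spec$d / k_c,
                                              paste0("monomer", tagged)))
  } else if (scenario == "two-well") {
    N <- get("N", 21L); kappa <- get("kappa", 3); k <- get("k", 2)
    dt <- get("dt", 0.01); cc <- get("c", (N %/% 2L) + 1L)
    spec <- polymer_spec(N = N, beta = 2, kappa = kappa, D = get("D", 1),
                         d = get("d", 3))
    wells <- list(well_spec(1L, k, rep(0, spec$d)),
                  well_spec(N, k, c(5, rep(0, spec$d - 1L))))
    tr <- simulate_polymer(spec, wells,
                           sim_config(dt = dt, n_steps = n_steps, seed = seed),
                           tagged = cc)
    f <- file.path(dir, sprintf("two_well_m%02d.csv", cc))
    write_locus_csv(tagged_locus(tr, cc), f, seed = seed, config = truth)
    files <- f
    est <- effective_stiffness_two_wells(wells, kappa, cc)
    truth$params <- list(N = N, kappa = kappa, k_n = k, k_m = k, n = 1L,
                         m = N, c = cc, dt = dt, n_steps = n_steps,
                         D = spec$D, d = spec$d,
                         mu_n = wells[[1L]]$mu, mu_m = wells[[2L]]$mu)
    truth$k_c <- est$value
    truth$variance <- spec$d / est$value
    truth$mean_position <- mean_position_two_wells(wells, kappa, cc)
  } else {  # free-chain
    N <- get("N", 30L); kappa <- get("kappa", 3); dt <- get("dt", 0.01)
    cc <- get("c", (N %/% 2L) + 1L)
    beta <- get("beta", 2)
    spec <- polymer_spec(N = N, beta = beta, kappa = kappa, D = get("D", 1),
                         d = get("d", 3))
    tr <- simulate_polymer(spec, list(),
                           sim_config(dt = dt, n_steps = n_steps, seed = seed),
                           tagged = cc)
    f <- file.path(dir, sprintf("free_chain_m%02d.csv", cc))
    write_locus_csv(tagged_locus(tr, cc), f, seed = seed, config = truth)
    files <- f
    truth$params <- list(N = N, beta = beta, kappa = kappa, c = cc, dt = dt,
                         n_steps = n_steps, D = spec$D, d = spec$d)
    truth$k_c <- 0
    truth$alpha <- anomalous_exponent(beta)
  }

  truth$files <- basename(files)
  truth_file <- file.path(dir, sprintf("%s_truth.json", gsub("-", "_", scenario)))
  jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(files = files, truth_file = truth_file, truth = truth))
}

#' Run the estimation pipeline over a batch of trajectories
#'
#' Applies the full trajectory analysis to every locus CSV in a directory
#' (or an explicit vector of files): diffusion estimate (unless `D` is
#' given), regression / moment / variance stiffness estimates,
#' autocorrelation with double-exponential fit, and -- when at least three
#' trajectories succeed -- the power-law fit of stiffness against variance
#' across the batch. Per-trajectory failures are caught and reported in the
#' output without aborting the batch.
#'
#' @param input a directory containing `*.csv` locus files, or a character
#'   vector of file paths.
#' @param out_dir optional output directory; when given, writes
#'   `estimates.csv`, `acf_fits.csv`, `powerlaw.json` and `pipeline_log.txt`
#'   (all stamped with package version, seed and config fingerprint).
#' @param D known diffusion coefficient, or `NULL` to estimate per
#'   trajectory.
#' @param axes coordinate subset to analyse (e.g. `c("x", "y")` for 3D
#'   microscopy data); `NULL` uses all columns.
#' @param max_lag_frames ACF lag span in frames (default `N_p/5`).
#' @param seed seed recorded in the provenance (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list: `estimates` (data frame), `acf_fits` (data frame),
#'   `powerlaw` (a [powerlaw_fit()] or `NULL`), `errors` (named list).
#' @export
run_pipeline <- function(input, out_dir = NULL, D = NULL, axes = NULL,
                         max_lag_frames = NULL, seed = NULL) {
  paths <- if (length(input) == 1L && dir.exists(input)) {
    sort(list.files(input, pattern = "\\.csv$", full.names = TRUE))
  } else {
    stopifnot(all(file.exists(input)))
    input
  }
  if (length(paths) == 0L)
    stop("no trajectory CSV files found in ", input, call. = FALSE)

  rows <- list(); acf_rows <- list(); errors <- list()
  for (p in paths) {
    res <- tryCatch({
      tr <- read_locus_csv(p)
      if (!is.null(axes)) tr <- project_axes(tr, axes)
      D_used <- D %||% estimate_diffusion(tr)
      reg <- estimate_stiffness_regression(tr, D_used)
      mom <- estimate_stiffness_moment(tr, D_used)
      varest <- estimate_stiffness_variance(tr)
      acf <- empirical_autocorrelation(tr, max_lag_frames)
      fit <- tryCatch(fit_double_exponential(acf), error = function(e) e)
      list(tr = tr, D = D_used, reg = reg, mom = mom, varest = varest,
           fit = fit)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[basename(p)]] <- conditionMessage(res)
      next
    }
    rows[[p]] <- data.frame(
      label = res$tr$label, file = basename(p),
      n_frames = nrow(res$tr$positions), d = ncol(res$tr$positions),
      D_used = res$D,
      k_c = res$reg$k_c, se = res$reg$se, method = "regression",
      k_c_moment = res$mom$k_c, k_c_variance = res$varest$k_c,
      variance = res$varest$variance)
    acf_rows[[p]] <- if (inherits(res$fit, "error")) {
      errors[[paste0(basename(p), ":acf")]] <- conditionMessage(res$fit)
      data.frame(label = res$tr$label, a1 = NA_real_, tau1 = NA_real_,
                 a2 = NA_real_, tau2 = NA_real_)
    } else {
      data.frame(label = res$tr$label, a1 = res$fit$a1, tau1 = res$fit$tau1,
                 a2 = res$fit$a2, tau2 = res$fit$tau2)
    }
  }
  if (length(rows) == 0L)
    stop("every trajectory failed; first error: ",
         errors[[1L]], call. = FALSE)
  estimates <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  acf_fits <- do.call(rbind, c(acf_rows, list(make.row.names = FALSE)))
  pl <- if (nrow(estimates) >= 3L &&
            all(estimates$k_c > 0 & estimates$variance > 0)) {
    powerlaw_fit(estimates$k_c, estimates$variance)
  } else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- provenance_header(seed, list(input = basename(paths), D = D,
                                        axes = axes))
    for (nm in c("estimates", "acf_fits")) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      con <- file(f, "w"); writeLines(hdr, con)
      utils::write.csv(get(nm), con, row.names = FALSE)
      close(con)
    }
    if (!is.null(pl))
      jsonlite::write_json(list(a = pl$a, b = pl$b, se = as.list(pl$se)),
                           file.path(out_dir, "powerlaw.json"),
                           auto_unbox = TRUE, digits = NA)
    writeLines(c(hdr, sprintf("processed %d/%d trajectories",
                              nrow(estimates), length(paths)),
                 if (length(errors))
                   paste("ERROR", names(errors),
                         unlist(errors))),
               file.path(out_dir, "pipeline_log.txt"))
  }
  structure(list(estimates = estimates, acf_fits = acf_fits, powerlaw = pl,
                 errors = errors),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d trajectories, %d error(s)\n",
              nrow(x$estimates), length(x$errors)))
  print(utils::head(x$estimates[, c("label", "n_frames", "k_c", "se",
                                    "k_c_variance", "variance")], 10L))
  if (!is.null(x$powerlaw)) print(x$powerlaw)
  invisible(x)
}
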