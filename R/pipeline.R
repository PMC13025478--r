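#' Reproduce a standard analysis target
#'
#' One-call reproduction of the package's reference analyses.  Every run
#' writes its data as CSV, a best-effort plot as PDF, and a JSON provenance
#' record (parameters, seed, package version, timestamp) next to the
#' outputs.  Acceptance of a reproduction is tied to the CSV values, not to
#' the plot rendering.
#'
#' Available targets:
#' \describe{
#'   \item{fig1}{projections \code{c0, c1, c2} of the slowest mode versus
#'     activity for cutoffs \code{Q = 25, 50, 100, 200}, with \code{q^1}
#'     and \code{q^(-1/8)} guide lines.}
#'   \item{fig2}{all decay-rate branches at \code{Q = 200} on log-log axes.}
#'   \item{fig2_inset}{cumulative exceptional-point count versus activity
#'     with its fitted square-root growth.}
#'   \item{fig3}{toy-model eigenvalues and fourth-component projections
#'     versus the control parameter at \code{c = 0.1}.}
#'   \item{table1}{the two-regime exponent table for polar and nematic
#'     interactions.}
#'   \item{exponents}{the \code{\link{exponent_table}} at default windows.}
#' }
#'
#' @param target one of the ids above.
#' @param outdir output directory (created if missing).
#' @param seed integer seed recorded in the provenance (the spectral
#'   targets are deterministic; the seed matters for future stochastic
#'   targets and is recorded regardless).
#' @param params named list of overrides (\code{Q}, windows, grid
#'   densities; see the target implementations).
#' @return invisibly, the list of files written.
#' @export
reproduce <- function(target, outdir = ".", seed = 1L, params = list()) {
  targets <- c("fig1", "fig2", "fig2_inset", "fig3", "table1", "exponents")
  if (!is.character(target) || length(target) != 1L || !target %in% targets)
    stop(sprintf("unknown target %s; valid targets: %s",
                 deparse(substitute(target)),
                 paste(targets, collapse = ", ")), call. = FALSE)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- switch(
    target,
    fig1 = reproduce_fig1(outdir, params),
    fig2 = reproduce_fig2(outdir, params),
    fig2_inset = reproduce_fig2_inset(outdir, params),
    fig3 = reproduce_fig3(outdir, params),
    table1 = reproduce_table1(outdir, params),
    exponents = reproduce_exponents(outdir, params))
  prov <- file.path(outdir, paste0(target, "_provenance.json"))
  write_provenance(prov, target = target, seed = seed, params = params,
                   outputs = basename(files))
  invisible(c(files, prov))
}

write_provenance <- function(path, ...) {
  rec <- list(..., package = "flockspec",
              version = as.character(utils::packageVersion("flockspec")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

pget <- function(params, name, default) {
  if (!is.null(params[[name]])) params[[name]] else default
}

reproduce_fig1 <- function(outdir, params) {
  Qs <- pget(params, "Q", c(25L, 50L, 100L, 200L))
  grid <- log_grid(pget(params, "window", c(1e-3, 1e4)),
                   pget(params, "points_per_decade", 8L))
  sw <- do.call(rbind, lapply(Qs, function(Q)
    cbind(Q = Q, sweep_spectrum(grid, Q, n_proj = 2L))))
  csv <- file.path(outdir, "fig1_projections.csv")
  utils::write.csv(sw, csv, row.names = FALSE)
  pdf_f <- file.path(outdir, "fig1_projections.pdf")
  grDevices::pdf(pdf_f, width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(NA, xlim = range(grid), ylim = c(1e-6, 1.5), log = "xy",
                 xlab = "activity q", ylab = "projection c_n",
                 main = "slowest-mode Fourier projections")
  cols <- seq_along(Qs)
  for (i in seq_along(Qs)) {
    s <- sw[sw$Q == Qs[i], ]
    graphics::lines(s$q, s$c0, col = cols[i], lty = 1)
    graphics::lines(s$q, pmax(s$c1, 1e-12), col = cols[i], lty = 2)
    graphics::lines(s$q, pmax(s$c2, 1e-12), col = cols[i], lty = 3)
  }
  graphics::lines(grid, 0.35 * grid, lty = 4)
  graphics::lines(grid, 0.6 * grid^(-1 / 8), lty = 4)
  graphics::legend("bottomleft", legend = paste0("Q=", Qs), col = cols,
                   lty = 1, cex = 0.8)
  c(csv, pdf_f)
}

reproduce_fig2 <- function(outdir, params) {
  Q <- pget(params, "Q", 200L)
  grid <- log_grid(pget(params, "window", c(1e-2, 1e4)),
                   pget(params, "points_per_decade", 10L))
  br <- track_branches(grid, Q, n_proj = 2L)
  csv <- file.path(outdir, "fig2_branches.csv")
  utils::write.csv(br, csv, row.names = FALSE)
  pdf_f <- file.path(outdir, "fig2_branches.pdf")
  grDevices::pdf(pdf_f, width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  nb <- pget(params, "n_branches_plot", 40L)
  sub <- br[br$branch < nb & br$re_lambda > 0, ]
  graphics::plot(NA, xlim = range(grid), ylim = range(sub$re_lambda),
                 log = "xy", xlab = "activity q", ylab = "Re lambda",
                 main = sprintf("decay-rate branches, Q = %d", Q))
  for (b in unique(sub$branch)) {
    s <- sub[sub$branch == b, ]
    graphics::lines(s$q, s$re_lambda, col = (b %% 2) + 1)
  }
  c(csv, pdf_f)
}

reproduce_fig2_inset <- function(outdir, params) {
  Q <- pget(params, "Q", 200L)
  q_max <- pget(params, "q_max", 2e3)
  eps <- suppressWarnings(
    scan_cascade(Q, q_max,
                 points_per_decade = pget(params, "points_per_decade", 60L),
                 tol = pget(params, "tol", 1e-4),
                 validate = pget(params, "validate", "mathieu")))
  fit <- fit_loglog_slope(eps$q_star, seq_len(nrow(eps)),
                          quantity = "ep_count")
  csv <- file.path(outdir, "fig2_inset_ep_count.csv")
  utils::write.csv(cbind(eps, N = seq_len(nrow(eps))), csv,
                   row.names = FALSE)
  pdf_f <- file.path(outdir, "fig2_inset_ep_count.pdf")
  grDevices::pdf(pdf_f, width = 5, height = 4)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(eps$q_star, seq_len(nrow(eps)), log = "xy",
                 xlab = "activity q", ylab = "N(q)",
                 main = sprintf("EP count, slope %.3f", fit$slope))
  graphics::lines(eps$q_star,
                  exp(fit$intercept) * eps$q_star^fit$slope, lty = 2)
  c(csv, pdf_f)
}

reproduce_fig3 <- function(outdir, params) {
  cc <- pget(params, "c", 0.1)
  grid <- log_grid(pget(params, "window", c(1e-1, 1e4)),
                   pget(params, "points_per_decade", 15L))
  sp <- toy_spectrum(grid, c = cc)
  csv <- file.path(outdir, "fig3_toy.csv")
  utils::write.csv(sp, csv, row.names = FALSE)
  pdf_f <- file.path(outdir, "fig3_toy.pdf")
  grDevices::pdf(pdf_f, width = 6, height = 7)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  graphics::plot(NA, xlim = range(grid), ylim = range(sp$re_lambda),
                 log = "x", xlab = "epsilon", ylab = "Re / Im lambda",
                 main = sprintf("toy model, c = %g", cc))
  for (i in 1:4) {
    s <- sp[sp$index == i, ]
    graphics::lines(s$epsilon, s$re_lambda, col = "blue")
    graphics::lines(s$epsilon, s$im_lambda, col = "orange")
  }
  graphics::plot(NA, xlim = range(grid), ylim = c(1e-3, 1), log = "xy",
                 xlab = "epsilon", ylab = "|v_4|")
  for (i in 1:4) {
    s <- sp[sp$index == i, ]
    graphics::lines(s$epsilon, pmax(s$p4, 1e-12), col = i)
  }
  graphics::lines(grid, 0.5 * grid^(-1 / 8), lty = 2)
  c(csv, pdf_f)
}

reproduce_table1 <- function(outdir, params) {
  tab <- table1_report(
    Q_low = pget(params, "Q_low", 50L),
    Q_high = pget(params, "Q_high", 400L),
    low_window = pget(params, "low_window", c(1e-3, 1e-2)),
    high_window = pget(params, "high_window", c(1e3, 1e4)),
    points_per_decade = pget(params, "points_per_decade", 20L))
  csv <- file.path(outdir, "table1_exponents.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  csv
}

reproduce_exponents <- function(outdir, params) {
  tab <- exponent_table(
    Q = pget(params, "Q", 50L),
    low_window = pget(params, "low_window", c(1e-3, 1e-2)),
    high_window = pget(params, "high_window", NULL),
    points_per_decade = pget(params, "points_per_decade", 20L))
  csv <- file.path(outdir, "exponents.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  csv
}

#' Run a declarative analysis configuration
#'
#' Executes a JSON configuration of the form
#' \preformatted{
#'   {"seed": 1, "outdir": "out",
#'    "tasks": [{"op": "reproduce", "args": {"target": "exponents"}},
#'              {"op": "exponent_table", "args": {"Q": 50,
#'                "low_window": [1e-3, 1e-2]}}]}
#' }
#' Each task's \code{op} must name an exported package function; its
#' \code{args} are passed as-is.  Data-frame results are written as
#' \code{task<i>_<op>.csv} in \code{outdir}.  A provenance record is
#' written even for an empty task list.  Schema violations are reported
#' with the offending task index.
#'
#' @param config_file path to the JSON configuration.
#' @return invisibly, the list of files written.
#' @export
run_config <- function(config_file) {
  cfg <- tryCatch(jsonlite::read_json(config_file, simplifyVector = TRUE),
                  error = function(e)
                    stop(sprintf("config parse error in '%s': %s",
                                 config_file, conditionMessage(e)),
                         call. = FALSE))
  outdir <- if (!is.null(cfg$outdir)) cfg$outdir else "."
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  tasks <- cfg$tasks
  if (is.null(tasks)) tasks <- list()
  if (is.data.frame(tasks)) tasks <- split(tasks, seq_len(nrow(tasks)))
  files <- character()
  for (i in seq_along(tasks)) {
    task <- tasks[[i]]
    if (is.data.frame(task)) task <- as.list(task)
    op <- task$op
    if (is.null(op) || !is.character(unlist(op)))
      stop(sprintf("config task %d: missing or non-string 'op'", i),
           call. = FALSE)
    op <- unlist(op)
    exported <- getNamespaceExports("flockspec")
    if (!op %in% exported)
      stop(sprintf("config task %d: unknown operation '%s'", i, op),
           call. = FALSE)
    args <- task$args
    if (is.null(args)) args <- list()
    if (is.data.frame(args)) args <- as.list(args)
    args <- lapply(args, function(a) if (is.list(a)) unlist(a) else a)
    res <- tryCatch(do.call(op, args),
                    error = function(e)
                      stop(sprintf("config task %d (%s): %s", i, op,
                                   conditionMessage(e)), call. = FALSE))
    if (is.data.frame(res)) {
      f <- file.path(outdir, sprintf("task%d_%s.csv", i, op))
      utils::write.csv(res, f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  prov <- file.path(outdir, "run_config_provenance.json")
  write_provenance(prov, config = config_file,
                   seed = if (is.null(cfg$seed)) NA else cfg$seed,
                   n_tasks = length(tasks), outputs = basename(files))
  invisible(c(files, prov))
}

#' Export a spectral sweep as CSV with JSON metadata
#'
#' Writes a \code{\link{sweep_spectrum}} or \code{\link{track_branches}}
#' result as CSV together with a JSON sidecar holding the run parameters
#' and package version.
#'
#' @param x data frame to export.
#' @param path CSV path; the metadata file replaces the extension with
#'   \code{.json}.
#' @param parameters named list stored in the metadata.
#' @return invisibly, both paths.
#' @export
export_results <- function(x, path, parameters = list()) {
  utils::write.csv(x, path, row.names = FALSE)
  meta <- sub("\\.[^.]*$", ".json", path)
  write_provenance(meta, parameters = parameters, rows = nrow(x))
  invisible(c(path, meta))
}
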