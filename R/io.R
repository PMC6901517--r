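fmt12 <- function(x) formatC(x, digits = 12, format = "g")

#' Read / write step-response CSV
#'
#' Two columns `time,activity` with header, optional third column
#' `stderr`; 12 significant digits, so write-then-read round-trips at the
#' declared precision.
#'
#' @param step a [step_response()].
#' @param path file path.
#' @param step_size recorded in a comment-free world via the sidecar; the
#'   reader takes it as an argument (default 1).
#' @export
write_step_csv <- function(step, path) {
  df <- data.frame(time = fmt12(step$time), activity = fmt12(step$activity))
  if (!is.null(step$stderr)) df$stderr <- fmt12(step$stderr)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_step_csv
#' @export
read_step_csv <- function(path, step_size = 1) {
  df <- utils::read.csv(path)
  if (!all(c("time", "activity") %in% names(df)))
    stop_config("step CSV must have columns time,activity")
  step_response(df$time, df$activity, step_size = step_size,
                stderr = df$stderr)
}

#' Read / write spectrum CSV
#'
#' Columns `omega,real,imag,amplitude,phase` (amplitude and phase are
#' derived and checked on read).
#'
#' @param spectrum a [response_spectrum()].
#' @param path file path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  df <- data.frame(omega = fmt12(spectrum$omega),
                   real = fmt12(Re(spectrum$value)),
                   imag = fmt12(Im(spectrum$value)),
                   amplitude = fmt12(spectrum_amplitude(spectrum)),
                   phase = fmt12(spectrum_phase(spectrum)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("omega", "real", "imag") %in% names(df)))
    stop_config("spectrum CSV must have columns omega,real,imag")
  response_spectrum(df$omega, complex(real = df$real, imaginary = df$imag))
}

#' Synthetic step-response fixtures
#'
#' Generates the exact (matrix-exponential) step response of the linear
#' two-node adaptive circuit — the cubic model with \eqn{c_3 = 0} and no
#' noise — plus optional additive Gaussian noise, together with a sidecar
#' of ground truth (\eqn{\epsilon}, plateau, \eqn{\omega^*}).  When
#' `omega_star` is given, \eqn{\tau_a = \tau_y} are solved so the phase
#' sign change lands exactly there (given `epsilon`).  Same spec + seed
#' produce identical output.
#'
#' @param kind `"adaptive_step"` (finite `epsilon`) or
#'   `"nonadaptive_step"` (a saturating, non-adapting single-pole ramp).
#' @param epsilon adaptation error parameter.
#' @param tau_a,tau_y circuit timescales (overridden by `omega_star`).
#' @param alpha2 sensitivity.
#' @param omega_star if non-NULL, place the phase sign change here.
#' @param noise additive Gaussian noise sd on the recorded activity.
#' @param dt,duration time grid.
#' @param seed RNG seed for the noise.
#' @param dir if non-NULL, write `step.csv` + `step.json` (sidecar) there.
#' @return a [step_response()] with attribute `truth` (list with
#'   `epsilon`, `plateau`, `omega_star`); file paths attached when written.
#' @export
generate_step_fixture <- function(kind = c("adaptive_step", "nonadaptive_step"),
                                  epsilon = 0.1, tau_a = 1, tau_y = 1,
                                  alpha2 = 1, omega_star = NULL, noise = 0,
                                  dt = 0.05, duration = 60, seed = 1L,
                                  dir = NULL) {
  kind <- match.arg(kind)
  if (!is.null(omega_star)) {
    if (epsilon >= 1) stop_config("epsilon must be < 1 to place omega_star")
    tau_a <- tau_y <- sqrt(1 - epsilon^2) / omega_star
  }
  t <- seq(0, duration, by = dt)
  if (kind == "adaptive_step") {
    # x = (a, y):  tau_a a' = -a + y + alpha2 ;  tau_y y' = -a - eps y
    M <- rbind(c(-1 / tau_a, 1 / tau_a), c(-1 / tau_y, -epsilon / tau_y))
    b <- c(alpha2 / tau_a, 0)
    xss <- -solve(M, b)
    eg <- eigen(M)
    V <- eg$vectors
    c0 <- solve(V, -xss)  # x(0) = 0
    a <- vapply(t, function(tt)
      Re((V %*% (c0 * exp(eg$values * tt)))[1, 1] + xss[1]), numeric(1))
    truth <- list(epsilon = epsilon,
                  plateau = alpha2 * epsilon / (1 + epsilon),
                  omega_star = sqrt((1 - epsilon^2 * tau_a / tau_y) /
                                      (tau_a * tau_y)))
  } else {
    a <- alpha2 * (1 - exp(-t / tau_a))  # saturating, never adapts
    truth <- list(epsilon = NA_real_, plateau = alpha2, omega_star = NA_real_)
  }
  if (noise > 0) {
    set.seed(seed)
    a <- a + rnorm(length(a), 0, noise)
    a <- a - a[1]  # keep causality anchor exact
  }
  st <- step_response(t, a, step_size = 1,
                      stderr = if (noise > 0) rep(noise, length(a)))
  attr(st, "truth") <- truth
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(dir, "step.csv"); js <- file.path(dir, "step.json")
    write_step_csv(st, csv)
    jsonlite::write_json(
      c(list(kind = kind, epsilon = epsilon, tau_a = tau_a, tau_y = tau_y,
             alpha2 = alpha2, noise = noise, dt = dt, duration = duration,
             seed = seed), truth),
      js, auto_unbox = TRUE, digits = NA)
    attr(st, "paths") <- c(csv = csv, json = js)
  }
  st
}

cli_usage <- function() {
  paste(
    "usage: dqs <subcommand> [options]",
    "subcommands:",
    "  fixtures     --kind adaptive_step --seed S --out DIR [--epsilon E]",
    "               [--omega-star W] [--noise N]",
    "  respond      --model cubic --epsilon E --tau-a X --tau-y Y --out FILE",
    "  onset        --spectrum FILE --tau-s X --alpha1 A1 --alpha2 A2 --out FILE",
    "  analyze-step --step FILE --tau-s X --alpha1 A1 --alpha2 A2 --out FILE",
    sep = "\n")
}

parse_cli_args <- function(args) {
  out <- list(); i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop_config("unexpected argument '%s'", args[i])
    key <- gsub("-", "_", substring(args[i], 3))
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop_config("missing value for --%s", key)
    out[[key]] <- args[i + 1]
    i <- i + 2
  }
  out
}

cli_provenance <- function(cmd, opts) {
  list(command = cmd, options = opts,
       package = "dqskit",
       version = as.character(utils::packageVersion("dqskit")))
}

#' Command-line entry point
#'
#' Dispatches the `dqs` subcommands (`fixtures`, `respond`, `onset`,
#' `analyze-step`).  All runs write a JSON result including a provenance
#' record.  Returns the exit code invisibly (0 success, 2 configuration /
#' usage error, 3 numerical failure); the installed wrapper script
#' `inst/cli/dqs` forwards it to the shell.
#'
#' @param args character vector, defaults to `commandArgs(TRUE)`.
#' @export
dqs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  run <- function() {
    if (!length(args)) stop_config("no subcommand given\n%s", cli_usage())
    cmd <- args[1]
    opts <- parse_cli_args(args[-1])
    num <- function(x, d = NULL) if (is.null(x)) d else as.numeric(x)
    switch(cmd,
      "fixtures" = {
        dir <- opts$out %||% "."
        st <- generate_step_fixture(
          kind = opts$kind %||% "adaptive_step",
          epsilon = num(opts$epsilon, 0.1),
          omega_star = num(opts$omega_star),
          noise = num(opts$noise, 0), dt = num(opts$dt, 0.05),
          duration = num(opts$duration, 60),
          seed = as.integer(num(opts$seed, 1)), dir = dir)
        jsonlite::write_json(cli_provenance(cmd, opts),
                             file.path(dir, "provenance.json"),
                             auto_unbox = TRUE)
      },
      "respond" = {
        if (is.null(opts$out)) stop_config("respond: --out required")
        p <- cubic_params(tau_a = num(opts$tau_a, 1), tau_y = num(opts$tau_y, 1),
                          epsilon = num(opts$epsilon, 0.1),
                          alpha2 = num(opts$alpha2, 1))
        ws <- as.numeric(omega_star(p))
        om <- seq(ws / 100, 5 * ws, length.out = 1000)
        write_spectrum_csv(cubic_response(p, om), opts$out)
      },
      "onset" = {
        if (is.null(opts$spectrum) || is.null(opts$out))
          stop_config("onset: --spectrum and --out required")
        sp <- read_spectrum_csv(opts$spectrum)
        sig <- signal_model(gamma = num(opts$tau_s, 1), K = 1,
                            alpha1 = num(opts$alpha1, 1))
        o <- onset_point(sp, sig, alpha2 = num(opts$alpha2, 1))
        jsonlite::write_json(
          c(o[c("status", "omega_o", "N_o", "Nbar_o", "period",
                "root_multiplicity")],
            list(provenance = cli_provenance(cmd, opts))),
          opts$out, auto_unbox = TRUE, digits = NA, na = "null")
      },
      "analyze-step" = {
        if (is.null(opts$step) || is.null(opts$out))
          stop_config("analyze-step: --step and --out required")
        st <- read_step_csv(opts$step)
        sig <- signal_model(gamma = num(opts$tau_s, 1e-4), K = 1,
                            alpha1 = num(opts$alpha1, 1))
        o <- onset_from_step(st, sig, alpha2 = num(opts$alpha2, 1))
        jsonlite::write_json(
          c(o[c("status", "omega_o", "N_o", "Nbar_o", "period",
                "adaptation_error")],
            list(provenance = cli_provenance(cmd, opts))),
          opts$out, auto_unbox = TRUE, digits = NA, na = "null")
      },
      stop_config("unknown subcommand '%s'\n%s", cmd, cli_usage()))
    0L
  }
  code <- tryCatch(run(),
    dqs_config_error = function(e) { message("config error: ",
                                             conditionMessage(e)); 2L },
    dqs_numerical_error = function(e) { message("numerical error: ",
                                                conditionMessage(e)); 3L },
    error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(code)
}
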