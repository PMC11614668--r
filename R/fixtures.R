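#' Ready-made experiment configurations
#'
#' Returns the fully resolved network and simulation settings for each of
#' the package's reference experiments, named after the simulation figures
#' they reproduce: single-cell voltage traces (`fig2_ra`, `fig2_int`), the
#' triggered interneuron (`fig3`), the uni- and bidirectional microcircuit
#' (`fig4`, `fig5`), the 50-neuron chain (`fig7`), the trigger-baseline
#' sweep (`fig9`), the first-edge conductance study (`fig10`), the
#' subcritical and supercritical chain conductances (`fig11`, `fig12`),
#' and the randomized per-edge chain (`fig13`).
#'
#' @param name Fixture name; an unknown name raises an error listing the
#'   available fixtures.
#' @param seed Integer seed for the randomized `fig13` construction
#'   (recorded in the fixture).
#' @return An object of class `hvc_fixture`: list with `name`, `network`
#'   (`hvc_network` or `NULL` for the analytic `fig9` sweep), `cfg`
#'   ([sim_config()] or `NULL`), and `extra` (fixture-specific values such
#'   as sweep factors or the drawn conductances).
#' @export
generate_fixture <- function(name, seed = 1L) {
  known <- c("fig2_ra", "fig2_int", "fig3", "fig4", "fig5", "fig7",
             "fig9", "fig10", "fig11", "fig12", "fig13")
  if (!is.character(name) || length(name) != 1L || !name %in% known) {
    stop("unknown fixture; available: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  fx <- switch(name,
    fig2_ra = list(
      network = build_single_neuron(ra_neuron_params(), i_background = 140),
      cfg = sim_config(duration = 500)),
    fig2_int = list(
      network = build_single_neuron(int_neuron_params(), i_background = 140),
      cfg = sim_config(duration = 500)),
    fig3 = list(
      network = hvc_network(
        list(neuron_entry(1L, int_neuron_params(), 250)),
        list(synapse_spec(0L, 1L, "GABA_A", 8)),
        trigger = trigger_params()),
      cfg = sim_config(duration = 120, settle = 50, record = c("v", "r"))),
    fig4 = list(
      network = build_microcircuit(bidirectional = FALSE),
      cfg = sim_config(duration = 120, settle = 50)),
    fig5 = list(
      network = build_microcircuit(bidirectional = TRUE),
      cfg = sim_config(duration = 120, settle = 50)),
    fig7 = list(
      network = build_chain_network(n_ra = 50, g_first = 10, g_chain = 8.2),
      cfg = sim_config(duration = 160, settle = 50)),
    fig9 = list(
      network = NULL, cfg = NULL,
      extra = list(trigger = unclass(trigger_params()),
                   factors = c(0.1, 1, 10))),
    fig10 = list(
      network = build_chain_network(n_ra = 2, g_first = 10),
      cfg = sim_config(duration = 60, settle = 50),
      extra = list(g_first_values = c(9.8, 9.9, 10, 10.3, 10.4))),
    fig11 = list(
      network = build_chain_network(n_ra = 50, g_chain = 8.18),
      cfg = sim_config(duration = 200, settle = 50)),
    fig12 = list(
      network = build_chain_network(n_ra = 50, g_chain = 8.27),
      cfg = sim_config(duration = 200, settle = 50)),
    fig13 = {
      seed <- as.integer(seed)
      g_draw <- withr_seed(seed, function() stats::runif(48, 8.1, 8.3))
      list(
        network = build_chain_network(n_ra = 50, g_first = 10,
                                      g_chain = g_draw),
        cfg = sim_config(duration = 160, settle = 50, seed = seed),
        extra = list(seed = seed, g_chain = g_draw))
    }
  )
  structure(c(list(name = name), fx), class = "hvc_fixture")
}

# Evaluate fn() under a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fn()
}

#' @export
print.hvc_fixture <- function(x, ...) {
  cat(sprintf("<hvc_fixture> %s\n", x$name))
  if (!is.null(x$network)) print(x$network)
  if (!is.null(x$cfg)) {
    cat(sprintf("  sim: %g ms at dt %g ms\n", x$cfg$duration, x$cfg$dt))
  }
  invisible(x)
}

#' Serialize a fixture to a config file
#'
#' @param fx An `hvc_fixture`.
#' @param path Output JSON path or connection (e.g. `stdout()`).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(fx, path) {
  stopifnot(inherits(fx, "hvc_fixture"))
  conf <- if (is.null(fx$network)) list() else
    network_to_config(fx$network, fx$cfg)
  conf$fixture <- fx$name
  if (!is.null(fx$extra)) conf$extra <- fx$extra
  txt <- jsonlite::toJSON(conf, auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  writeLines(txt, path)
  invisible(path)
}
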