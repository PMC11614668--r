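#' Serialize a network and simulation settings to a config list
#'
#' The config is a plain nested list (blocks `neurons`, `synapses`,
#' `trigger`, `release`, `sim`) that maps one-to-one onto the JSON file
#' format used by [write_network_config()] and the command-line tool.
#' Loading a written config reproduces the simulation bit-exactly.
#'
#' @param net An `hvc_network`.
#' @param cfg A [sim_config()], or `NULL` to omit the `sim` block.
#' @return A nested list.
#' @export
network_to_config <- function(net, cfg = NULL) {
  neurons <- lapply(net$neurons, function(n) {
    p <- n$params
    gates <- lapply(p$gates, function(g) unclass(g))
    scalars <- p[setdiff(names(p), c("kind", "gates"))]
    list(id = n$id, kind = p$kind, i_background = n$i_background,
         v0 = n$v0, params = scalars, gates = gates)
  })
  synapses <- lapply(net$synapses, function(s) {
    list(source = s$source, target = s$target,
         receptor = s$receptor$kind, alpha = s$receptor$alpha,
         beta = s$receptor$beta, e_rev = s$receptor$e_rev,
         g_max = s$g_max)
  })
  out <- list(neurons = neurons, synapses = synapses,
              trigger = if (!is.null(net$trigger)) unclass(net$trigger),
              release = unclass(net$release))
  if (!is.null(cfg)) out$sim <- unclass(cfg)
  out
}

#' Rebuild a network (and simulation settings) from a config list
#'
#' @param conf A list as produced by [network_to_config()] or parsed from a
#'   config file.
#' @return A list with `network` (`hvc_network`) and `cfg` ([sim_config()]
#'   or `NULL` when the config has no `sim` block).
#' @export
config_to_network <- function(conf) {
  need <- function(x, field, where) {
    if (is.null(x[[field]])) {
      stop(sprintf("config field '%s.%s' is missing", where, field),
           call. = FALSE)
    }
    x[[field]]
  }
  if (is.null(conf$neurons)) stop("config field 'neurons' is missing",
                                  call. = FALSE)
  neurons <- lapply(seq_along(conf$neurons), function(i) {
    n <- conf$neurons[[i]]
    where <- sprintf("neurons[%d]", i)
    kind <- need(n, "kind", where)
    ctor <- switch(kind, HVC_RA = ra_neuron_params, HVC_I = int_neuron_params,
                   stop(sprintf("config field '%s.kind' must be HVC_RA or HVC_I",
                                i), call. = FALSE))
    p <- do.call(ctor, n$params %||% list())
    if (!is.null(n$gates)) {
      for (g in names(n$gates)) {
        p$gates[[g]] <- do.call(gating_spec, n$gates[[g]])
      }
      validate_neuron_params(p)
    }
    neuron_entry(need(n, "id", where), p, need(n, "i_background", where),
                 v0 = n$v0)
  })
  synapses <- lapply(seq_along(conf$synapses), function(i) {
    s <- conf$synapses[[i]]
    where <- sprintf("synapses[%d]", i)
    rp <- receptor_params(need(s, "receptor", where), alpha = s$alpha,
                          beta = s$beta, e_rev = s$e_rev)
    synapse_spec(need(s, "source", where), need(s, "target", where),
                 rp, need(s, "g_max", where))
  })
  trigger <- if (!is.null(conf$trigger)) do.call(trigger_params, conf$trigger)
  release <- if (!is.null(conf$release)) do.call(release_params, conf$release)
  net <- hvc_network(neurons, synapses, trigger = trigger,
                     release = release %||% release_params())
  cfg <- NULL
  if (!is.null(conf$sim)) {
    s <- conf$sim
    cfg <- sim_config(duration = need(s, "duration", "sim"),
                      dt = s$dt %||% 0.02,
                      record = unlist(s$record %||% "v"),
                      settle = s$settle %||% 0,
                      seed = s$seed)
  }
  list(network = net, cfg = cfg)
}

#' Write / read a network config file (JSON)
#'
#' Full-precision JSON (no digit rounding), so a config survives a
#' write/read round trip with bit-identical simulations.
#'
#' @param net An `hvc_network`.
#' @param path File path.
#' @param cfg Optional [sim_config()] stored in the `sim` block.
#' @return `write_network_config()` returns `path` invisibly;
#'   `read_network_config()` returns a list with `network` and `cfg`.
#' @export
write_network_config <- function(net, path, cfg = NULL) {
  jsonlite::write_json(network_to_config(net, cfg), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  conf <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  config_to_network(conf)
}

#' Export recorded traces as delimited text
#'
#' Tab-separated: a `time` column (ms) plus one column per recorded
#' channel (voltages `v_<id>`, optionally receptor fractions and calcium).
#'
#' @param traces An `hvc_traces`.
#' @param path Output file.
#' @param every Keep every `every`-th sample (decimation for plotting);
#'   default 1 = native resolution.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, every = 1L) {
  keep <- seq(1L, length(traces$time), by = as.integer(every))
  df <- data.frame(time = traces$time[keep], traces$v[keep, , drop = FALSE],
                   check.names = FALSE)
  if (!is.null(traces$r)) {
    r <- traces$r[keep, , drop = FALSE]
    colnames(r) <- paste0("r_", seq_len(ncol(r)))
    df <- cbind(df, r)
  }
  if (!is.null(traces$ca)) {
    ca <- traces$ca[keep, , drop = FALSE]
    colnames(ca) <- paste0("ca_", seq_len(ncol(ca)))
    df <- cbind(df, ca)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a spike table as delimited text
#'
#' @param spikes Data frame from [spike_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(spikes, path) {
  utils::write.table(spikes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
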