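#' @export
print.trial_events <- function(x, ...) {
  cat(sprintf("<trial_events> %d events (%s); run: %d scans @ TR %.3f s\n",
              nrow(x),
              paste(sprintf("%s: %d", names(table(x$trial_type)),
                            as.integer(table(x$trial_type))), collapse = ", "),
              attr(x, "n_scans"), attr(x, "tr")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' @export
print.beta_series <- function(x, ...) {
  cat(sprintf("<beta_series> %d %s nodes x %d trials (%s)\n",
              nrow(x$betas), x$node_type, ncol(x$betas),
              paste(unique(x$trial_type), collapse = "/")))
  invisible(x)
}

#' @export
print.connectivity_graph <- function(x, ...) {
  thr <- if (is.null(x$threshold)) {
    "unthresholded"
  } else {
    sprintf("FDR q = %g, %d edges kept", x$threshold$q,
            x$threshold$n_edges_kept)
  }
  cat(sprintf("<connectivity_graph> %d nodes, %d trials, %s\n",
              nrow(x$W), x$n_trials, thr))
  invisible(x)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d nodes in %d modules, Q = %.4f (gamma = %g, %d restarts)\n",
              length(x$membership), max(x$membership), x$Q, x$gamma,
              x$n_restarts))
  invisible(x)
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s: %d nodes, df = %d, t in [%.2f, %.2f]\n",
              x$contrast, length(x$t), x$df,
              min(x$t, na.rm = TRUE), max(x$t, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.forgetting_summary <- function(x, ...) {
  g <- x$group
  cat(sprintf("<forgetting_summary> %d subjects\n", nrow(x$per_subject)))
  for (nm in c("overall", "cued", "uncued")) {
    cat(sprintf("  %-7s delta = %+.3f +/- %.3f cm, t(%d) = %s, p = %s\n",
                nm, g[[nm]]$mean, g[[nm]]$sem, g[[nm]]$df,
                format(g[[nm]]$t, digits = 3),
                format(g[[nm]]$p, digits = 3)))
  }
  cat(sprintf("  cued vs uncued: F(1,%d) = %s, p = %s\n",
              g$cued_vs_uncued$df, format(g$cued_vs_uncued$F, digits = 3),
              format(g$cued_vs_uncued$p, digits = 3)))
  invisible(x)
}

#' @export
print.roi_correction <- function(x, ...) {
  cat(sprintf("<roi_correction> %d ROIs, BH critical p = %g (q = %g)\n",
              nrow(x$table), x$critical_p, x$q))
  print(x$table, ...)
  invisible(x)
}
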