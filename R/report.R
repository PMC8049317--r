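#' Run the full missingness-assessment pipeline and write a report bundle
#'
#' Non-interactive equivalent of a missingness dashboard session:
#' profiles the matrix, imputes it with the chosen method, sweeps the
#' missingness thresholds comparing imputed against non-imputed
#' densities, builds the two Mapper topologies at `tau_mapper`, and
#' writes every table as CSV/JSON, the figures as PNG, a machine-readable
#' manifest, and a static HTML page that embeds them. All JSON/CSV
#' outputs are deterministic functions of the inputs and `seed`.
#'
#' @param non_imputed A [protein_matrix()] or a path accepted by
#'   [load_matrix()].
#' @param out_dir Output directory (created).
#' @param method Imputation method, see [impute()]. Default
#'   `"lowest_value"`.
#' @param params Method parameters for [impute()].
#' @param thresholds Threshold sweep grid.
#' @param tau_mapper Missingness threshold applied before the Mapper
#'   stage.
#' @param mapper_cfg A [mapper_config()].
#' @param protein Optional protein id for a single-protein comparison.
#' @param seed Integer seed for every stochastic stage.
#' @param make_plots Emit PNG figures (skipped automatically if no
#'   bitmap device is available).
#' @return Invisibly, a list with the in-memory results (`profile`,
#'   `imputation`, `sweep`, `mapper_non_imputed`, `mapper_imputed`,
#'   `topology_comparison`, `files`).
#' @export
run_report <- function(non_imputed, out_dir,
                       method = "lowest_value", params = list(),
                       thresholds = seq(0.05, 0.95, by = 0.05),
                       tau_mapper = 0.8,
                       mapper_cfg = mapper_config(),
                       protein = NULL, seed = 1, make_plots = TRUE) {
  stage <- "input"
  on_fail <- function(e) {
    stop(sprintf("report failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    m <- if (is_protein_matrix(non_imputed)) non_imputed else
      load_matrix(non_imputed)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)

    stage <- "profile"
    prof <- profile_missingness(m)
    files <- c(files, write_profile(prof, out_dir))
    if (make_plots) {
      files <- c(files, file.path(out_dir, "histograms.png"))
      plot_profile(prof, file.path(out_dir, "histograms.png"))
    }

    stage <- "impute"
    imp <- impute(m, method = method, params = params, seed = seed)
    write_matrix(imp$completed, file.path(out_dir, "imputed.tsv"))
    files <- c(files, file.path(out_dir, "imputed.tsv"))

    stage <- "compare"
    sweep_tab <- threshold_sweep(m, imp$completed, taus = thresholds)
    if (is.null(sweep_tab)) stop("no feasible threshold in the sweep")
    utils::write.csv(sweep_tab, file.path(out_dir, "threshold_sweep.csv"),
                     row.names = FALSE)
    jsonlite::write_json(sweep_tab, file.path(out_dir, "threshold_sweep.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, file.path(out_dir, c("threshold_sweep.csv",
                                           "threshold_sweep.json")))
    if (make_plots) {
      for (tau in range(sweep_tab$tau)) {
        tc <- compare_at_threshold(m, imp$completed, tau)
        pth <- file.path(out_dir, sprintf("density_tau_%03d.png",
                                          round(100 * tau)))
        plot_comparison(tc, pth)
        files <- c(files, pth)
      }
    }
    prot_rec <- NULL
    if (!is.null(protein)) {
      stage <- "compare_protein"
      prot_rec <- compare_protein(m, imp$completed, protein)
      jsonlite::write_json(
        prot_rec[c("protein_id", "missing_fraction", "peak_non_imputed",
                   "peak_imputed", "peak_distance", "ks_D", "ks_p")],
        file.path(out_dir, "protein_comparison.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c(files, file.path(out_dir, "protein_comparison.json"))
    }

    stage <- "mapper"
    m_f <- filter_by_threshold(m, tau_mapper)
    if (ncol(m_f$values) == 0) {
      stop(sprintf("tau_mapper = %g keeps no protein", tau_mapper))
    }
    imp_f <- subset_matrix(imp$completed, proteins = m_f$protein_ids)
    g_ni <- detect_communities(enrich_missingness(
      build_mapper(m_f, mapper_cfg, seed = seed), prof))
    g_im <- detect_communities(enrich_missingness(
      build_mapper(imp_f, mapper_cfg, seed = seed), prof))
    topo <- compare_topologies(g_ni, g_im)
    write_mapper_graph(g_ni, file.path(out_dir, "mapper_non_imputed.graphml"),
                       file.path(out_dir, "mapper_non_imputed.json"))
    write_mapper_graph(g_im, file.path(out_dir, "mapper_imputed.graphml"),
                       file.path(out_dir, "mapper_imputed.json"))
    jsonlite::write_json(topo, file.path(out_dir, "topology_comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, file.path(out_dir, c(
      "mapper_non_imputed.graphml", "mapper_non_imputed.json",
      "mapper_imputed.graphml", "mapper_imputed.json",
      "topology_comparison.json")))
    if (make_plots) {
      plot_mapper(g_ni, file.path(out_dir, "mapper_non_imputed.png"),
                  seed = seed, main = "Mapper: non-imputed")
      plot_mapper(g_im, file.path(out_dir, "mapper_imputed.png"),
                  seed = seed, main = sprintf("Mapper: imputed (%s)", method))
      files <- c(files, file.path(out_dir, c("mapper_non_imputed.png",
                                             "mapper_imputed.png")))
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("protmiss")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = seed,
      config = list(method = method, params = params,
                    thresholds = thresholds, tau_mapper = tau_mapper,
                    mapper = unclass(mapper_cfg), protein = protein))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, file.path(out_dir, "manifest.json"))

    stage <- "html"
    write_report_html(out_dir, prof, sweep_tab, topo, method, tau_mapper,
                      prot_rec, make_plots)
    files <- c(files, file.path(out_dir, "report.html"))

    invisible(list(profile = prof, imputation = imp, sweep = sweep_tab,
                   mapper_non_imputed = g_ni, mapper_imputed = g_im,
                   topology_comparison = topo, files = files))
  }, error = on_fail)
}

html_table <- function(df, digits = 4) {
  fmt <- function(v) if (is.numeric(v)) formatC(v, digits = digits,
                                                format = "g") else v
  cells <- vapply(seq_len(nrow(df)), function(i) {
    paste0("<tr>", paste0("<td>", vapply(df[i, ], fmt, ""),
                          "</td>", collapse = ""), "</tr>")
  }, "")
  paste0("<table border='1' cellpadding='3'><tr>",
         paste0("<th>", names(df), "</th>", collapse = ""),
         "</tr>", paste(cells, collapse = "\n"), "</table>")
}

write_report_html <- function(out_dir, prof, sweep_tab, topo, method,
                              tau_mapper, prot_rec, make_plots) {
  img <- function(f) {
    if (make_plots && file.exists(file.path(out_dir, f)))
      sprintf("<p><img src='%s' width='650'></p>", f) else ""
  }
  parts <- c(
    "<html><head><title>Missingness assessment report</title></head><body>",
    "<h1>Missingness assessment report</h1>",
    "<h2>Missingness profile</h2>",
    sprintf("<p>Overall missing fraction: %.4f. Per-sample range: %.4f&ndash;%.4f. Complete proteins: %d of %d.</p>",
            prof$overall_fraction, prof$sample_fraction_range[1],
            prof$sample_fraction_range[2], prof$n_complete_proteins,
            length(prof$per_protein_fraction)),
    img("histograms.png"),
    sprintf("<h2>Threshold sweep (imputation: %s)</h2>", method),
    html_table(sweep_tab),
    img(sprintf("density_tau_%03d.png", round(100 * min(sweep_tab$tau)))),
    img(sprintf("density_tau_%03d.png", round(100 * max(sweep_tab$tau)))),
    if (!is.null(prot_rec)) c(
      sprintf("<h2>Protein %s</h2>", prot_rec$protein_id),
      sprintf("<p>Missing fraction %.4f; peak distance %.4f; KS D = %.4f, p = %.4g.</p>",
              prot_rec$missing_fraction, prot_rec$peak_distance,
              prot_rec$ks_D, prot_rec$ks_p)) else NULL,
    sprintf("<h2>Topology comparison (tau = %.2f)</h2>", tau_mapper),
    sprintf("<p>Non-imputed: %d nodes, %d edges, %d components. Imputed: %d nodes, %d edges, %d components. Adjusted Rand index of the sample partitions: %.4f.</p>",
            topo$summary_non_imputed$n_nodes, topo$summary_non_imputed$n_edges,
            topo$summary_non_imputed$n_connected_components,
            topo$summary_imputed$n_nodes, topo$summary_imputed$n_edges,
            topo$summary_imputed$n_connected_components,
            topo$adjusted_rand_index),
    img("mapper_non_imputed.png"),
    img("mapper_imputed.png"),
    "</body></html>")
  writeLines(parts, file.path(out_dir, "report.html"))
  invisible(NULL)
}
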