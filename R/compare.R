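#' Default configuration for a two-structure comparison
#'
#' Carries every cutoff and probe of the pipeline with its standard value:
#' 4.0 Angstrom H-bond cutoff with 3.5 Angstrom strong class, 0.5 Angstrom
#' grid spacing, 1.4 Angstrom surface probe and 0.9 Angstrom tunnel probe.
#' The default residue pairs of interest are the key ion-pathway contacts
#' (Asp116-Arg244, Ser73-Asp116, Tyr106-His225, Tyr222-Trp102,
#' Tyr222-Gln218); pairs absent from a structure are reported as `NA`.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `compare_config`.
#' @export
compare_config <- function(...) {
  cfg <- list(
    cutoff = 4.0, strict = 3.5,
    water_policy = "include_water_water",
    spacing = 0.5, probe = 1.4, tunnel_probe = 0.9, padding = 4,
    residue_pairs = data.frame(
      name = c("Asp116-Arg244", "Ser73-Asp116", "Tyr106-His225",
               "Tyr222-Trp102", "Tyr222-Gln218"),
      resA = c(116L, 73L, 106L, 222L, 222L),
      resB = c(244L, 116L, 225L, 102L, 218L),
      stringsAsFactors = FALSE),
    displacement_residues = c(66L),
    seed = "auto",           # tunnel seed: "auto" or xyz vector
    run_pore = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- c("compare_config", "list")
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("comparison stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full comparative analysis of two structures
#'
#' Executes census, sequence alignment, superposition, H-bond graphs,
#' difference graph, key distances and (optionally) cavity/tunnel analysis,
#' and collects everything in one deterministic report.
#'
#' @param A,B `pore_structure` objects, or paths to coordinate files.
#' @param config A [compare_config()].
#' @return Object of class `comparison_report`: nested list with elements
#'   `census`, `sequence`, `superposition`, `graphs`, `difference`,
#'   `distances`, `displacements`, `pore`, `parameters`.
#' @export
run_compare <- function(A, B, config = compare_config()) {
  if (is.character(A)) A <- .stage("parse_A", parse_structure(A))
  if (is.character(B)) B <- .stage("parse_B", parse_structure(B))

  census <- .stage("census", list(A = entity_census(A), B = entity_census(B)))
  map <- .stage("correspondence", structure_map(A, B))
  sp_ca <- .stage("superposition", superpose_structures(A, B, map, "CA"))
  sp_heavy <- .stage("superposition", superpose_structures(A, B, map, "heavy"))

  graphs <- .stage("hbond_graphs", {
    gA <- build_graph(detect_hbonds(A, config$cutoff), A, config$water_policy)
    gB <- build_graph(detect_hbonds(B, config$cutoff), B, config$water_policy)
    list(A = gA, B = gB,
         summary_A = summarize_graph(gA), summary_B = summarize_graph(gB))
  })
  diffg <- .stage("difference_graph",
                  difference_graph(graphs$A, graphs$B, map))

  distances <- .stage("distances", {
    rp <- config$residue_pairs
    if (nrow(rp)) {
      rp$dist_A <- rp$dist_B <- NA_real_
      for (i in seq_len(nrow(rp))) {
        rp$dist_A[i] <- tryCatch(
          min_sidechain_distance(A, rp$resA[i], rp$resB[i]),
          error = function(e) NA_real_)
        rp$dist_B[i] <- tryCatch(
          min_sidechain_distance(B, rp$resA[i], rp$resB[i]),
          error = function(e) NA_real_)
      }
    }
    rp
  })

  displacements <- .stage("displacements", {
    data.frame(resno = config$displacement_residues,
               displacement_A = vapply(config$displacement_residues,
                 function(r) tryCatch(
                   residue_displacement(A, B, map, r, frame = sp_ca),
                   error = function(e) NA_real_), numeric(1)))
  })

  pore <- NULL
  if (isTRUE(config$run_pore)) {
    pore <- .stage("pore", {
      one <- function(s) {
        g <- rasterize(s, spacing = config$spacing, padding = config$padding)
        cf <- clearance_field(g)
        cav <- find_cavities(g, probe = config$probe, clearance = cf)
        seed <- if (identical(config$seed, "auto")) {
          tryCatch(conduction_seed(s), error = function(e) {
            a <- s$atoms[!s$atoms$hetero, ]
            colMeans(a[, c("x", "y", "z")])
          })
        } else config$seed
        tun <- tunnel_search(g, seed, probe = config$tunnel_probe,
                             clearance = cf)
        list(volumes = cav$volumes, n_cavities = length(cav$volumes),
             tunnel_found = tun$found,
             bottleneck_radius = tun$bottleneck_radius, seed = seed)
      }
      list(A = one(A), B = one(B))
    })
  }

  structure(list(
    ids = c(A = A$id, B = B$id),
    census = census,
    sequence = list(identity_pct = map$identity_pct,
                    similarity_pct = map$similarity_pct,
                    n_pairs = nrow(map$pairs),
                    unmatched_A = length(map$unmatchedA),
                    unmatched_B = length(map$unmatchedB)),
    superposition = list(rmsd_ca = sp_ca$rmsd, rmsd_heavy = sp_heavy$rmsd,
                         n_ca = sp_ca$n_atoms, n_heavy = sp_heavy$n_atoms),
    graphs = list(summary_A = graphs$summary_A, summary_B = graphs$summary_B),
    difference = list(
      n_conserved = nrow(diffg$conserved),
      n_unique_A = nrow(diffg$unique_A),
      n_unique_B = nrow(diffg$unique_B),
      unique_A = diffg$unique_A, unique_B = diffg$unique_B,
      conserved = diffg$conserved),
    distances = distances,
    displacements = displacements,
    pore = pore,
    parameters = config[c("cutoff", "strict", "water_policy", "spacing",
                          "probe", "tunnel_probe")]),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: %s vs %s\n", x$ids["A"], x$ids["B"]))
  cat(sprintf("  identity %.1f%%, similarity %.1f%% over %d aligned pairs\n",
              x$sequence$identity_pct, x$sequence$similarity_pct,
              x$sequence$n_pairs))
  cat(sprintf("  rmsd: %.3f A (CA, n=%d), %.3f A (heavy, n=%d)\n",
              x$superposition$rmsd_ca, x$superposition$n_ca,
              x$superposition$rmsd_heavy, x$superposition$n_heavy))
  cat(sprintf("  H-bond edges: %d (A) / %d (B); conserved %d\n",
              x$graphs$summary_A["total_edges"],
              x$graphs$summary_B["total_edges"], x$difference$n_conserved))
  if (!is.null(x$pore))
    cat(sprintf("  tunnel: %s (A) / %s (B)\n",
                x$pore$A$tunnel_found, x$pore$B$tunnel_found))
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits `report.json` (machine readable, deterministic) and `report.md`
#' (human readable) into a directory.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c(
    sprintf("# Comparison: %s vs %s", report$ids["A"], report$ids["B"]),
    "",
    sprintf("- identity: %.1f%%, similarity: %.1f%%",
            report$sequence$identity_pct, report$sequence$similarity_pct),
    sprintf("- RMSD: %.3f A (CA), %.3f A (all heavy)",
            report$superposition$rmsd_ca, report$superposition$rmsd_heavy),
    sprintf("- H-bond edges: %d in A (%d water-mediated), %d in B (%d water-mediated)",
            report$graphs$summary_A["total_edges"],
            report$graphs$summary_A["water_mediated_edges"],
            report$graphs$summary_B["total_edges"],
            report$graphs$summary_B["water_mediated_edges"]),
    sprintf("- difference graph: %d conserved, %d unique to A, %d unique to B",
            report$difference$n_conserved, report$difference$n_unique_A,
            report$difference$n_unique_B))
  if (!is.null(report$pore)) {
    md <- c(md, sprintf("- tunnel (probe %.1f A): %s in A, %s in B",
                        report$parameters$tunnel_probe,
                        report$pore$A$tunnel_found, report$pore$B$tunnel_found))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Download deposited models from the PDB
#'
#' Network helper, clearly separated from the analysis: nothing else in the
#' package (and none of the tests except the full reproduction check) calls
#' it.
#'
#' @param ids Character vector of PDB accessions (e.g. `c("8GI8", "8GI9")`).
#' @param dir Output directory.
#' @param timeout Per-file timeout, seconds.
#' @return Character vector of mmCIF file paths.
#' @export
fetch_pdb <- function(ids, dir = tempdir(), timeout = 60) {
  vapply(ids, function(id) {
    dest <- file.path(dir, paste0(tolower(id), ".cif"))
    if (!file.exists(dest)) {
      url <- sprintf("https://files.rcsb.org/download/%s.cif", toupper(id))
      old <- getOption("timeout"); on.exit(options(timeout = old))
      options(timeout = timeout)
      utils::download.file(url, dest, quiet = TRUE, mode = "wb")
    }
    dest
  }, character(1))
}
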