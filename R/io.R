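# Readers and writers for the pipeline's plain-text formats (rotated
# genotype CSV, TSV trait and result tables, 8/16-bit TIFF), plus the
# pipeline configuration and the end-to-end driver.

#' Write / read a genotype matrix with its map (rotated CSV)
#'
#' Dialect: a header row \code{marker,chromosome,position_cM,<line ids...>},
#' then one row per marker with its name, chromosome, cM position and the
#' A/B/- genotype code of every line.
#'
#' @param genotypes Character matrix lines x markers ("A"/"B", NA or "-").
#' @param map Genetic map for those markers.
#' @param path Output/input file.
#' @return \code{read_genotype_csv}: list with \code{map} and
#'   \code{genotypes}.
#' @export
write_genotype_csv <- function(genotypes, map, path) {
  validate_map(map)
  g <- t(genotypes[, map$marker, drop = FALSE])
  g[is.na(g)] <- "-"
  df <- data.frame(marker = map$marker, chromosome = map$chromosome,
                   position_cM = map$position_cM, g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[-(1:3)] <- rownames(genotypes)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_csv
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("marker", "chromosome", "position_cM")
  if (!all(req %in% names(df))) {
    stop("genotype CSV must start with columns ", paste(req, collapse = ", "))
  }
  map <- df[, req]
  class(map) <- c("genetic_map", "data.frame")
  validate_map(map)
  line_ids <- setdiff(names(df), req)
  if (!length(line_ids)) stop("genotype CSV has no line columns")
  g <- as.matrix(df[, line_ids, drop = FALSE])
  bad <- which(matrix(!(g %in% c("A", "B", "-")), nrow(g)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("unknown genotype code '%s' at marker %s, line %s",
                 g[bad[1, 1], bad[1, 2]], map$marker[bad[1, 1]],
                 line_ids[bad[1, 2]]))
  }
  g[g == "-"] <- NA
  genotypes <- t(g)
  rownames(genotypes) <- line_ids
  colnames(genotypes) <- map$marker
  list(map = map, genotypes = genotypes)
}

#' Write / read a per-nucleus trait table (TSV)
#'
#' Required id columns: \code{line_id, plant_id, nucleus_id}; every other
#' column is a trait. Numeric values round-trip to 6 significant digits.
#' Extra columns are preserved with a warning on read.
#'
#' @param table Trait table.
#' @param path File path.
#' @param required Id columns a valid table must carry.
#' @return \code{read_trait_table}: the table as a \code{data.frame}.
#' @export
write_trait_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path,
                             required = c("line_id", "plant_id", "nucleus_id")) {
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse trait table: ",
                                          conditionMessage(e)))
  if (!all(required %in% names(df))) {
    stop("trait table missing required column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "))
  }
  extra <- setdiff(names(df)[!vapply(df, is.numeric, logical(1))], required)
  if (length(extra)) {
    warning("non-numeric extra column(s) preserved: ",
            paste(extra, collapse = ", "))
  }
  df
}

#' Write an 8-bit image or a 16-bit label mask as TIFF
#'
#' @param image Numeric matrix on the 0-255 scale, or an integer label
#'   matrix for \code{write_label_mask}.
#' @param mask Integer label matrix (values < 65536).
#' @param path File path.
#' @return \code{read_image_tiff}: numeric matrix on the 0-255 scale;
#'   \code{read_label_mask}: integer matrix.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(image / 255, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  round(x * 255)
}

#' @rdname write_image_tiff
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(max(mask) < 65536)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_label_mask <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
}

#' Write a correlation network as an edge-list TSV and GraphML
#'
#' @param network Output of \code{\link{correlation_network}}.
#' @param tsv_path Edge-list TSV path (trait_a, trait_b, r, p, stars).
#' @param graphml_path Optional GraphML path for external viewers.
#' @return Invisibly, the edge list.
#' @export
write_network <- function(network, tsv_path, graphml_path = NULL) {
  utils::write.table(network$edges, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(graphml_path) && nrow(network$edges) > 0) {
    g <- igraph::graph_from_data_frame(
      network$edges[, c("trait_a", "trait_b", "r", "p")], directed = FALSE)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(network$edges)
}

#' Pipeline configuration
#'
#' One nested list carrying every stage's parameters plus the global seed;
#' unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param seed Global seed; every stage derives its randomness from it.
#' @param out_dir Output directory for all artifacts.
#' @param n_lines RIL population size.
#' @param n_chrom,chrom_length_cM,marker_step_cM Map layout.
#' @param qtl \code{data.frame(chromosome, position_cM, effect)} of planted
#'   QTL (simulation stages).
#' @param sigma_line,sigma_nucleus,n_nuclei_per_line,n_plants_per_line
#'   Trait-simulation variance structure and sampling depth.
#' @param n_images,image_shape,nuclei_per_image Image-rendering batch.
#' @param segmentation A \code{\link{segmentation_config}}.
#' @param cim A \code{\link{cim_config}}.
#' @param outlier_rule Outlier rule for per-line aggregation.
#' @param min_nuclei,min_plants Line inclusion thresholds.
#' @param nils Optional NIL definition table for the confirmation stage.
#' @param nil_n Per-group sample size when simulating NIL trait values.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("chromomorph_run_"),
                            n_lines = 46, n_chrom = 5, chrom_length_cM = 100,
                            marker_step_cM = 5,
                            qtl = data.frame(chromosome = 2, position_cM = 40,
                                             effect = 1),
                            sigma_line = 1, sigma_nucleus = 2,
                            n_nuclei_per_line = 30, n_plants_per_line = 2,
                            n_images = 2, image_shape = c(192, 192),
                            nuclei_per_image = 4,
                            segmentation = segmentation_config(),
                            cim = cim_config(n_permutations = 200),
                            outlier_rule = "percentile95",
                            min_nuclei = 26, min_plants = 2,
                            nils = NULL, nil_n = 30) {
  if (cim$n_permutations < 20) stop("n_permutations must be at least 20")
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  cfg
}

#' Run the full synthetic pipeline
#'
#' Simulates the RIL population and trait table, renders and segments a
#' small image batch (nucleus/chromocenter tables), aggregates per line,
#' computes heritability, runs the CIM scan with its permutation threshold,
#' calls QTL, and (when a NIL table is supplied) simulates NIL phenotypes
#' from the planted model and confirms the calls. Every artifact is written
#' under \code{out_dir} together with a manifest recording the
#' configuration and file checksums; the same configuration and seed yield
#' a byte-identical manifest.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisible list with the in-memory results (\code{trait_table},
#'   \code{line_summaries}, \code{heritability}, \code{scan},
#'   \code{morphometry}, \code{confirmations}, \code{manifest_path}).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  map <- make_genetic_map(config$n_chrom, config$chrom_length_cM,
                          config$marker_step_cM)
  geno <- simulate_ril_genotypes(map, config$n_lines, seed = config$seed)
  write_genotype_csv(geno, map, out("genotypes.csv"))

  traits <- simulate_trait_values(geno, map, config$qtl,
                                  sigma_line = config$sigma_line,
                                  sigma_nucleus = config$sigma_nucleus,
                                  n_nuclei_per_line = config$n_nuclei_per_line,
                                  n_plants_per_line = config$n_plants_per_line,
                                  seed = config$seed + 1, trait = "trait")
  write_trait_table(traits, out("trait_table.tsv"))

  # image batch: render, segment, measure
  morpho <- list()
  for (i in seq_len(config$n_images)) {
    truths <- random_nucleus_truths(config$nuclei_per_image,
                                    config$image_shape,
                                    seed = config$seed + 100 + i)
    fld <- render_nucleus_image(truths, config$image_shape,
                                seed = config$seed + 200 + i)
    write_image_tiff(fld$image, out(sprintf("field_%02d.tif", i)))
    nm <- segment_nuclei(fld$image, config$segmentation)
    cm <- segment_chromocenters(fld$image, nm, config$segmentation)
    write_label_mask(nm, out(sprintf("field_%02d_nuclei.tif", i)))
    write_label_mask(cm, out(sprintf("field_%02d_cc.tif", i)))
    if (max(nm) > 0) morpho[[i]] <- measure_image(fld$image, nm, cm)
  }
  nuc_tab <- do.call(rbind, lapply(seq_along(morpho), function(i) {
    if (is.null(morpho[[i]])) return(NULL)
    cbind(field = i, morpho[[i]]$nuclei)
  }))
  cc_tab <- do.call(rbind, lapply(seq_along(morpho), function(i) {
    if (is.null(morpho[[i]]$chromocenters)) return(NULL)
    cbind(field = i, morpho[[i]]$chromocenters)
  }))
  if (!is.null(nuc_tab)) {
    nuc_tab$nuc_density <- nuc_tab$nuc_intensity  # column alias
    utils::write.table(nuc_tab, out("nuclei.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(cc_tab)) {
    cc_tab$density <- cc_tab$intensity
    utils::write.table(cc_tab, out("chromocenters.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  ls <- line_summary(traits, min_nuclei = min(config$min_nuclei,
                                              config$n_nuclei_per_line),
                     min_plants = min(config$min_plants,
                                      config$n_plants_per_line),
                     outlier_rule = config$outlier_rule)
  utils::write.table(ls, out("line_summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  h2 <- heritability(traits, "trait")
  utils::write.table(h2, out("heritability.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  pheno <- stats::setNames(ls$mean[ls$trait == "trait"],
                           ls$line_id[ls$trait == "trait"])
  grid <- genotype_probs(map, geno, step_cM = config$cim$step_cM)
  cim <- config$cim
  cim$seed <- config$seed + 300
  scan <- qtl_scan(grid, pheno, cim)
  utils::write.table(scan$profile, out("lod_profile.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  calls <- scan$calls
  utils::write.table(calls, out("qtl_calls.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("threshold\t%.6f", scan$threshold$threshold),
               sprintf("n_permutations\t%d", scan$threshold$n_permutations),
               sprintf("alpha\t%g", scan$threshold$alpha),
               sprintf("seed\t%d", cim$seed)),
             out("threshold.tsv"))

  confirmations <- NULL
  if (!is.null(config$nils) && nrow(calls) > 0) {
    nils <- nil_definitions(config$nils)
    set.seed(config$seed + 400)
    effects <- do.call(rbind, lapply(unique(nils$nil_id), function(id) {
      ints <- nils[nils$nil_id == id, , drop = FALSE]
      shift <- 0
      for (q in seq_len(nrow(config$qtl))) {
        cover <- any(ints$chromosome == config$qtl$chromosome[q] &
                       ints$start_cM <= config$qtl$position_cM[q] &
                       ints$end_cM >= config$qtl$position_cM[q])
        # donor introgression flips the planted A effect to -effect
        if (cover) shift <- shift - 2 * config$qtl$effect[q]
      }
      classify_effect(stats::rnorm(config$nil_n, shift, config$sigma_nucleus),
                      stats::rnorm(config$nil_n, 0, config$sigma_nucleus),
                      nil_id = id, trait = "trait")
    }))
    confirmations <- lapply(seq_len(nrow(calls)), function(i) {
      confirm_qtl(calls[i, ], nils = nils, effect_calls = effects)
    })
    conf_tab <- do.call(rbind, lapply(seq_along(confirmations), function(i) {
      cf <- confirmations[[i]]
      data.frame(calls[i, ], status = cf$status,
                 explaining_nils = paste(cf$explaining_nils, collapse = ";"),
                 refined = paste(sprintf("%g-%g", cf$refined$start_cM,
                                         cf$refined$end_cM), collapse = ";"))
    }))
    utils::write.table(conf_tab, out("nil_confirmation.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  strip <- function(x) {
    if (is.data.frame(x)) return(lapply(unclass(x), strip))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  cfg_flat <- strip(unclass(config))
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    package = "chromomorph",
    seed = config$seed,
    config = cfg_flat[setdiff(names(cfg_flat), "out_dir")],
    files = as.list(tools::md5sum(file.path(config$out_dir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(trait_table = traits, line_summaries = ls,
                 heritability = h2, scan = scan,
                 morphometry = list(nuclei = nuc_tab, chromocenters = cc_tab),
                 confirmations = confirmations,
                 manifest_path = out("manifest.json")))
}
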