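# Table readers/writers (TSV dialect: tab-separated, header row, UTF-8,
# '.' decimal, no quoting of numeric fields), GFF3 gene-model ingestion,
# and the pipeline configuration / runner.

read_tsv_strict <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE)
}

write_tsv_plain <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read / write the pipeline's tabular inputs and outputs
#'
#' Readers validate the expected columns; writers emit plain
#' tab-separated text with a header row so that every writer/reader pair
#' round-trips exactly.
#'
#' * counts: `gene_id`, `sample_id`, `count`
#' * annotation: `gene_id`, `length_bp`, plus optional `chrom`,
#'   `overlap_partner`, `shared_bp`
#' * design: `sample_id`, `strain`
#' * GO annotation: `gene_id`, `term_id`
#' * PPI edges: `protein_a`, `protein_b`, `score`
#' * histone ratios: `gene_id` plus one column per modification
#' * genotype: `locus`, `state`
#'
#' @param path File path.
#' @return A tibble (readers) or the path, invisibly (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_counts_tsv <- function(path) {
  assert_cols(read_tsv_strict(path, readr::cols(
    gene_id = readr::col_character(), sample_id = readr::col_character(),
    count = readr::col_integer())),
    c("gene_id", "sample_id", "count"), "counts file")
}

#' @rdname table_io
#' @param x Table to write.
#' @export
write_counts_tsv <- function(x, path) write_tsv_plain(x, path)

#' @rdname table_io
#' @export
read_annotation_tsv <- function(path) {
  assert_cols(readr::read_tsv(path, progress = FALSE,
                              show_col_types = FALSE),
              c("gene_id", "length_bp"), "annotation file")
}

#' @rdname table_io
#' @export
write_annotation_tsv <- function(x, path) write_tsv_plain(x, path)

#' @rdname table_io
#' @export
read_design_tsv <- function(path) {
  assert_cols(read_tsv_strict(path, readr::cols(
    sample_id = readr::col_character(), strain = readr::col_character())),
    c("sample_id", "strain"), "design file")
}

#' @rdname table_io
#' @export
write_design_tsv <- function(x, path) write_tsv_plain(x, path)

#' @rdname table_io
#' @export
read_go_tsv <- function(path) {
  assert_cols(read_tsv_strict(path, readr::cols(
    gene_id = readr::col_character(), term_id = readr::col_character())),
    c("gene_id", "term_id"), "GO annotation file")
}

#' @rdname table_io
#' @export
write_go_tsv <- function(x, path) write_tsv_plain(x, path)

#' @rdname table_io
#' @export
read_ppi_tsv <- function(path) {
  assert_cols(read_tsv_strict(path, readr::cols(
    protein_a = readr::col_character(),
    protein_b = readr::col_character(),
    score = readr::col_double())),
    c("protein_a", "protein_b", "score"), "PPI edge file")
}

#' @rdname table_io
#' @export
write_ppi_tsv <- function(x, path) write_tsv_plain(x, path)

#' @rdname table_io
#' @export
read_histone_tsv <- function(path) {
  assert_cols(readr::read_tsv(path, progress = FALSE,
                              show_col_types = FALSE),
              "gene_id", "histone ratio file")
}

#' @rdname table_io
#' @export
write_histone_tsv <- function(x, path) write_tsv_plain(x, path)

#' @rdname table_io
#' @export
read_genotype_tsv <- function(path) {
  diploid_genotype(assert_cols(read_tsv_strict(path, readr::cols(
    locus = readr::col_character(), state = readr::col_character())),
    c("locus", "state"), "genotype file"))
}

#' @rdname table_io
#' @export
write_genotype_tsv <- function(x, path) {
  write_tsv_plain(select(as_tibble(x), "locus", "state"), path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene features from a GFF3 file (1-based inclusive coordinates,
#' so `length_bp = end - start + 1`), and detects same-strand overlapping
#' gene pairs, reporting the shared span in base pairs.  Lines that do not
#' have the nine GFF3 fields raise an error naming the line number.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type to keep (default `"gene"`; set `NULL`
#'   to keep everything).
#' @return A list with `genes` (tibble: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `length_bp`, `overlap_partner`, `shared_bp`),
#'   `pairs` (tibble: `gene_a`, `gene_b`, `shared_bp`) and `annotation`
#'   (the tibble consumed by [rpkm_normalize()]).
#' @examples
#' \donttest{
#' gff <- system.file("extdata", "example_genes.gff3",
#'                    package = "esterdeg")
#' models <- read_gff3(gff)
#' models$pairs  # GENE_A and GENE_B overlap by 301 bp on the + strand
#' }
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  for (pkg in c("rtracklayer", "GenomicRanges", "S4Vectors")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(sprintf("package '%s' is required for GFF3 input", pkg))
    }
  }
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length,
               integer(1))
  if (any(nf != 9L)) {
    abort(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields",
                  body[which(nf != 9L)[1]]))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(feature_type) && "type" %in%
      names(S4Vectors::mcols(gr))) {
    keep <- as.character(S4Vectors::mcols(gr)$type) == feature_type
    if (any(keep)) gr <- gr[keep]
  }
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
  if (is.null(ids)) ids <- sprintf("feature_%d", seq_along(gr))
  ids <- as.character(ids)
  genes <- tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    length_bp = GenomicRanges::width(gr),
    overlap_partner = NA_character_,
    shared_bp = NA_integer_)
  hits <- GenomicRanges::findOverlaps(gr, ignore.strand = FALSE,
                                      drop.self = TRUE,
                                      drop.redundant = TRUE)
  pairs <- tibble(gene_a = character(), gene_b = character(),
                  shared_bp = integer())
  if (length(hits) > 0L) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    shared <- GenomicRanges::width(GenomicRanges::pintersect(gr[qi],
                                                             gr[si]))
    pairs <- tibble(gene_a = ids[qi], gene_b = ids[si],
                    shared_bp = as.integer(shared))
    genes$overlap_partner[qi] <- ids[si]
    genes$overlap_partner[si] <- ids[qi]
    genes$shared_bp[qi] <- as.integer(shared)
    genes$shared_bp[si] <- as.integer(shared)
  }
  list(genes = genes, pairs = pairs,
       annotation = select(genes, "gene_id", "length_bp", "chrom",
                           "overlap_partner", "shared_bp"))
}

#' Write gene models to a GFF3 file
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates, GFF3 convention).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  assert_cols(genes, c("gene_id", "chrom", "start", "end", "strand"),
              "genes")
  lines <- c("##gff-version 3",
             sprintf("%s\testerdeg\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Validated configuration for a full synthetic pipeline run
#'
#' Collects every stage parameter of the pipeline with range validation;
#' unknown keys are rejected.
#'
#' @param seed Global integer seed, expanded into per-generator child
#'   seeds.
#' @param alpha DEG adjusted-p cutoff.
#' @param fc_threshold DEG fold-change cutoff (linear scale).
#' @param correction `"bh"` or `"holm"`.
#' @param levene_alpha Homoscedasticity-gate level.
#' @param pseudocount RPKM pseudo-count for fold changes.
#' @param cut_height PPI dendrogram cut height.
#' @param min_cluster_size,min_cluster_score PPI retention thresholds.
#' @param histone_alpha Histone-enrichment call level.
#' @param go_alpha GO-enrichment call level.
#' @param ... Unknown keys: an error.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, alpha = 0.05, fc_threshold = 2,
                            correction = "bh", levene_alpha = 0.05,
                            pseudocount = 0.1, cut_height = 0.95,
                            min_cluster_size = 10, min_cluster_score = 0.4,
                            histone_alpha = 0.05, go_alpha = 0.05, ...) {
  extra <- list(...)
  if (length(extra) > 0L) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(names(extra), collapse = ", ")))
  }
  for (nm in c("alpha", "levene_alpha", "histone_alpha", "go_alpha")) {
    assert_scalar_number(get(nm), nm, min = 0, max = 1)
  }
  assert_scalar_number(fc_threshold, "fc_threshold", min = 1)
  assert_scalar_number(cut_height, "cut_height", min = 0, max = 2)
  assert_scalar_number(min_cluster_score, "min_cluster_score", 0, 1)
  if (!correction %in% c("bh", "holm")) {
    abort("`correction` must be 'bh' or 'holm'")
  }
  structure(list(seed = assert_count(seed, "seed", min = 0L),
                 alpha = alpha, fc_threshold = fc_threshold,
                 correction = correction, levene_alpha = levene_alpha,
                 pseudocount = pseudocount, cut_height = cut_height,
                 min_cluster_size = min_cluster_size,
                 min_cluster_score = min_cluster_score,
                 histone_alpha = histone_alpha, go_alpha = go_alpha),
            class = "pipeline_config")
}

#' Run the full synthetic pipeline end to end
#'
#' Generates a complete synthetic study from the configured seed
#' (two-strain counts with knockouts and one overlapping ORF pair, a GO
#' annotation, a blocked PPI edge list, shifted histone ratios), then runs
#' overlap correction, RPKM normalization, DEG calling, GO enrichment (on
#' up, down and combined DEG sets), PPI clustering and histone enrichment,
#' and assembles a reproducibility manifest (package and R versions, seed,
#' parameters, and — when outputs are written — file checksums).
#'
#' @param config A [pipeline_config()].
#' @param scenario Optional list overriding the default synthetic scenario
#'   (fields of [count_sim_spec()] plus `ppi_spec`, `histone_spec`).
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as TSV/JSON files.
#' @return A list of class `pipeline_run` with elements `sim`, `deg`,
#'   `go` (list: up/down/all), `ppi`, `histone` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), scenario = list(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  spec_args <- list(
    n_genes = 2000, n_replicates_per_strain = 3,
    dispersion = 50, n_up = 120, n_down = 15, effect_log2fc = 2,
    knockout_genes = sprintf("g%04d", 1:4),
    overlap_pair = list(gene_a = "g0001", gene_b = "g0005",
                        shared_fraction = 0.5),
    seed = config$seed)
  spec_args[names(scenario)[names(scenario) %in% names(spec_args)]] <-
    scenario[names(scenario) %in% names(spec_args)]
  cspec <- do.call(count_sim_spec, spec_args)
  sim <- simulate_counts(cspec)

  counts <- subtract_overlap(sim$counts, sim$region_counts %||%
                               tibble(gene_a = character(),
                                      gene_b = character(),
                                      sample_id = character(),
                                      a_unique = integer(),
                                      b_unique = integer(),
                                      shared = integer()),
                             sim$annotation)
  rpkm <- rpkm_normalize(counts, sim$annotation)
  deg <- deg_test(rpkm, sim$design, alpha = config$alpha,
                  fc_threshold = config$fc_threshold,
                  correction = config$correction,
                  levene_alpha = config$levene_alpha,
                  pseudocount = config$pseudocount)

  universe <- deg$gene_id
  de_up <- deg$gene_id[deg$deg_class == "up"]
  de_down <- deg$gene_id[deg$deg_class == "down"]
  de_all <- c(de_up, de_down)
  gspec <- go_sim_spec(
    n_terms = 40, term_size_range = c(10, 120),
    planted_enriched_terms = tibble(
      term_id = "T_planted", size = min(60L, max(2L, length(de_all))),
      de_overlap = min(50L, length(de_all))),
    seed = config$seed)
  go_annot <- simulate_go_annotation(gspec, universe, de_all)
  go <- purrr::map(
    list(up = de_up, down = de_down, all = de_all),
    function(q) {
      if (length(q) == 0L) return(NULL)
      enrich(go_annot, q, universe = universe,
             correction = config$correction, alpha = config$go_alpha)
    })

  pspec <- scenario$ppi_spec %||%
    ppi_sim_spec(n_proteins = 70, block_sizes = c(12, 12, 10),
                 seed = config$seed)
  edges <- simulate_ppi(pspec)
  ppi <- ppi_cluster(edges, cut_height = config$cut_height,
                     min_size = config$min_cluster_size,
                     min_score = config$min_cluster_score)

  classes <- sim$truth %>%
    mutate(class = dplyr::case_when(
      .data$class %in% c("up", "down") ~ .data$class,
      .data$class == "knockout" ~ "down",
      TRUE ~ "ns"))
  hspec <- scenario$histone_spec %||%
    histone_sim_spec(shift_up = 0.3, shift_down = -0.3,
                     shift_mods = histone_modifications()[1:7],
                     seed = config$seed)
  ratios <- simulate_histone(hspec, classes)
  histone <- histone_enrich(ratios, classes, alpha = config$histone_alpha)

  manifest <- list(
    package = "esterdeg",
    package_version = as.character(utils::packageVersion("esterdeg")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = unclass(config),
    deg_summary = as.list(glance(deg)),
    files = list())

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      counts = write_counts_tsv(counts, file.path(out_dir, "counts.tsv")),
      deg = write_tsv_plain(as_tibble(deg),
                            file.path(out_dir, "deg_results.tsv")),
      ppi = write_tsv_plain(tidy(ppi),
                            file.path(out_dir, "ppi_clusters.tsv")),
      histone = write_tsv_plain(as_tibble(histone),
                                file.path(out_dir, "histone.tsv")))
    jsonlite::write_json(as.list(glance(deg)),
                         file.path(out_dir, "deg_summary.json"),
                         auto_unbox = TRUE)
    paths <- c(paths, summary = file.path(out_dir, "deg_summary.json"))
    manifest$files <- as.list(tools::md5sum(unname(paths)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(sim = sim, counts_corrected = counts, rpkm = rpkm,
                 deg = deg, go = go, ppi = ppi, histone = histone,
                 manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- attr(x$deg, "summary")
  cat(sprintf(
    "pipeline run (seed %d): %d genes tested, %d up / %d down DEGs\n",
    x$manifest$seed, s$n_tested, s$n_up, s$n_down))
  cat(sprintf("PPI: %d clusters, %d retained; histone: %d/%d enriched (up)\n",
              nrow(x$ppi), sum(x$ppi$retained),
              sum(x$histone$call == "enriched" &
                    x$histone$gene_class == "up"),
              sum(x$histone$gene_class == "up")))
  invisible(x)
}
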