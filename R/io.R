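#' Read and write the screen's tabular interchange formats
#'
#' Plain-TSV readers/writers for phenotype tables, pool manifests and
#' per-pool read counts. All readers validate the column layout and report
#' malformed lines with their line numbers. Sites are keyed as
#' `"chrom:pos:ref:alt"` with 1-based positions (VCF convention); BED
#' intervals are 0-based half-open, and conversion between the two is
#' centralised in [bed_start_to_vcf_pos()] / [vcf_pos_to_bed_start()].
#'
#' @param x Object to write (tibble / pool_design).
#' @param path File path.
#' @return Readers return tibbles (the manifest reader a `pool_design`);
#'   writers return `path` invisibly.
#' @name screen_io
NULL

stop_malformed <- function(path, problems) {
  if (nrow(problems)) {
    abort(sprintf("malformed input in %s (line %d): %s", path,
                  problems$row[1] + 1L, problems$expected[1]))
  }
}

read_checked <- function(path, col_types) {
  x <- readr::read_tsv(path, col_types = col_types)
  stop_malformed(path, readr::problems(x))
  miss <- setdiff(names(col_types$cols), names(x))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  }
  x
}

#' @rdname screen_io
#' @export
write_phenotypes <- function(x, path) {
  readr::write_tsv(x[c("id", "status", "age_at_diagnosis")], path, na = "")
  invisible(path)
}

#' @rdname screen_io
#' @param onset_cutoff Age cutoff used to derive the onset group.
#' @export
read_phenotypes <- function(path, onset_cutoff = 40) {
  x <- read_checked(path, readr::cols(id = "c", status = "c",
                                      age_at_diagnosis = "d"))
  bad <- which(!x$status %in% c("case", "control"))
  if (length(bad)) {
    abort(sprintf("malformed input in %s (line %d): status must be case/control",
                  path, bad[1] + 1L))
  }
  x |>
    dplyr::mutate(onset_group = dplyr::case_when(
      .data$status == "control" ~ "control",
      .data$age_at_diagnosis < onset_cutoff ~ "early",
      TRUE ~ "late"))
}

#' @rdname screen_io
#' @export
write_pool_manifest <- function(x, path) {
  x |>
    dplyr::group_by(.data$pool_id) |>
    dplyr::summarise(stage = .data$stage[1], stratum = .data$stratum[1],
                     members = paste(sort(.data$id), collapse = ","),
                     .groups = "drop") |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_pool_manifest <- function(path) {
  x <- read_checked(path, readr::cols(pool_id = "c", stage = "i",
                                      stratum = "c", members = "c"))
  x |>
    dplyr::mutate(id = strsplit(.data$members, ",")) |>
    tidyr::unnest("id") |>
    dplyr::select("pool_id", "stage", "stratum", "id") |>
    dplyr::arrange(.data$pool_id, .data$id) |>
    new_pool_design()
}

#' @rdname screen_io
#' @export
write_pool_counts <- function(x, path) {
  cols <- intersect(c("pool_id", "site", "exon", "pool_size", "depth",
                      "alt_count"), names(x))
  readr::write_tsv(x[cols], path)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_pool_counts <- function(path) {
  x <- read_checked(path, readr::cols(pool_id = "c", site = "c",
                                      depth = "i", alt_count = "i",
                                      .default = readr::col_guess()))
  if (any(x$alt_count > x$depth)) {
    abort(sprintf("malformed input in %s (line %d): alt_count > depth",
                  path, which(x$alt_count > x$depth)[1] + 1L))
  }
  x
}

#' Write pooled allele-count calls as VCF
#'
#' One pseudo-sample per pool; INFO carries cohort AC/AN/AF, and the
#' per-pool estimated allele count and quality travel in `PC`/`PQ` FORMAT
#' fields. Positions are 1-based (VCF convention), parsed from the
#' `"chrom:pos:ref:alt"` site key.
#'
#' @param calls Per-pool calls ([call_allele_counts()] output).
#' @param variants Variant table ([discover_variants()] output); only its
#'   sites are written.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, variants, path) {
  pools <- sort(unique(calls$pool_id))
  key <- stringr::str_split_fixed(variants$site, ":", 4)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=poolscreen",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Cohort alt allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Chromosomes in depth-passing pools\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Cohort alt allele frequency\">",
    "##FORMAT=<ID=PC,Number=1,Type=Integer,Description=\"Estimated pool alt allele count\">",
    "##FORMAT=<ID=PQ,Number=1,Type=Float,Description=\"log10 LR of call vs zero count\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pools), collapse = "\t"))
  wide_pc <- calls |>
    dplyr::filter(.data$site %in% variants$site) |>
    dplyr::mutate(cell = sprintf("%d:%.2f", .data$est_count, .data$quality)) |>
    dplyr::select("site", "pool_id", "cell") |>
    tidyr::pivot_wider(names_from = "pool_id", values_from = "cell",
                       values_fill = ".") |>
    dplyr::select("site", dplyr::all_of(pools))
  wide_pc <- wide_pc[match(variants$site, wide_pc$site), ]
  body <- paste(
    key[, 1], key[, 2], variants$site, key[, 3], key[, 4], ".", "PASS",
    sprintf("AC=%d;AN=%d;AF=%.6g", variants$ac, variants$an, variants$af),
    "PC:PQ",
    apply(as.matrix(wide_pc[, -1, drop = FALSE]), 1, paste, collapse = "\t"),
    sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read pooled calls back from a VCF
#'
#' Uses `VariantAnnotation::readVcf()` (required at call time) and returns
#' the variant-level table plus per-pool estimated counts.
#'
#' @param path VCF path written by [write_calls_vcf()].
#' @return List with `variants` (site, ac, an, af) and `pool_counts`
#'   (site, pool_id, est_count) tibbles.
#' @export
read_calls_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("read_calls_vcf() needs the VariantAnnotation package.")
  }
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  variants <- tibble::tibble(site = rownames(vcf),
                             ac = as.integer(info$AC),
                             an = as.integer(info$AN),
                             af = as.numeric(info$AF))
  pc <- VariantAnnotation::geno(vcf)$PC
  pool_counts <- tibble::tibble(
    site = rep(rownames(pc), ncol(pc)),
    pool_id = rep(colnames(pc), each = nrow(pc)),
    est_count = suppressWarnings(as.integer(as.vector(pc)))) |>
    dplyr::filter(!is.na(.data$est_count))
  list(variants = variants, pool_counts = pool_counts)
}

#' BED target regions
#'
#' Targets are stored as BED (0-based half-open); in memory they are
#' 1-based closed intervals matching the site keys. Reading uses
#' `rtracklayer::import()`.
#'
#' @param targets Tibble with chrom, start (1-based), end, name.
#' @param path BED path.
#' @return `read_target_bed()` returns the 1-based tibble; the writer
#'   returns `path` invisibly.
#' @export
write_target_bed <- function(targets, path) {
  readr::write_tsv(
    tibble::tibble(chrom = targets$chrom,
                   start = vcf_pos_to_bed_start(targets$start),
                   end = targets$end,
                   name = targets$name %||% "."),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_target_bed
#' @export
read_target_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_target_bed() needs the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),  # already 1-based in GRanges
                 end = GenomicRanges::end(gr),
                 name = gr$name %||% ".")
}

#' Coordinate conventions
#'
#' VCF positions are 1-based; BED starts are 0-based half-open. BED start
#' 100 corresponds to VCF position 101.
#'
#' @param pos,start Integer vectors.
#' @return Converted integer vector.
#' @export
bed_start_to_vcf_pos <- function(start) as.integer(start) + 1L

#' @rdname bed_start_to_vcf_pos
#' @export
vcf_pos_to_bed_start <- function(pos) as.integer(pos) - 1L
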