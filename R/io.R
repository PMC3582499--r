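## Readers and writers for the formats the pipeline consumes: Genepop for
## codominant population markers, plain TSV dialects for marker tables,
## genotype matrices, phenotypes and inviability blocks.

#' Read a Genepop file
#'
#' Parses the standard Genepop dialect: a title line, one locus name per line
#' (or a single comma-separated line), and `POP` blocks of individuals
#' (`id , 0101 0202 ...`) with 2- or 3-digit allele codes where `00`/`000`
#' marks a missing allele. Populations are labelled `pop_1`, `pop_2`, ... in
#' file order.
#'
#' @param path Path to the file.
#' @return A long tibble with columns `population`, `individual`, `locus`,
#'   `allele_1`, `allele_2` (integer allele codes, `NA` = missing).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) abort("not a Genepop file: fewer than 3 lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop))
    abort("not a Genepop file: no POP line found")
  header <- trimws(lines[2:(first_pop - 1)])
  loci <- if (length(header) == 1 && grepl(",", header)) {
    trimws(strsplit(header, ",")[[1]])
  } else {
    header[nzchar(header)]
  }
  n_loci <- length(loci)
  if (n_loci == 0) abort("no locus names between the title and the first POP")

  rows <- list()
  pop_id <- 0L
  for (i in seq(first_pop, length(lines))) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (toupper(line) == "POP") {
      pop_id <- pop_id + 1L
      next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) != 2)
      abort(sprintf("line %d: expected 'id , genotypes'", i))
    id <- trimws(parts[1])
    gts <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
    if (length(gts) != n_loci)
      abort(sprintf("line %d: %d genotypes but %d loci declared",
                    i, length(gts), n_loci))
    width <- unique(nchar(gts))
    if (length(width) != 1 || !width %in% c(4L, 6L))
      abort(sprintf("line %d: genotypes must be 4 or 6 digits", i))
    half <- width / 2
    a1 <- as.integer(substr(gts, 1, half))
    a2 <- as.integer(substr(gts, half + 1, width))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    rows[[length(rows) + 1]] <- tibble(
      population = sprintf("pop_%d", pop_id), individual = id,
      locus = loci, allele_1 = a1, allele_2 = a2)
  }
  if (length(rows) == 0) abort("no individuals found after POP lines")
  dplyr::bind_rows(rows)
}

#' Write a marker table as a Genepop file
#'
#' @inheritParams locus_stats
#' @param path Output path.
#' @param title Title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(data, path, title = "sweeplink marker export") {
  loci <- unique(data$locus)
  digits <- if (max(c(data$allele_1, data$allele_2), na.rm = TRUE) > 99) 3L
    else 2L
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = digits, flag = "0")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, loci), con)
  wide <- data %>%
    dplyr::mutate(gt = paste0(fmt(.data$allele_1), fmt(.data$allele_2))) %>%
    dplyr::select("population", "individual", "locus", "gt") %>%
    tidyr::pivot_wider(names_from = "locus", values_from = "gt")
  for (p in unique(wide$population)) {
    writeLines("POP", con)
    block <- wide[wide$population == p, ]
    writeLines(paste0(block$individual, " , ",
                      apply(block[, loci, drop = FALSE], 1, paste,
                            collapse = " ")), con)
  }
  invisible(path)
}

#' Read and write the TSV marker dialect
#'
#' Columns `population`, `individual`, `locus`, `allele_1`, `allele_2`, with
#' 0 coding a missing allele.
#'
#' @param path Path to the file.
#' @return [read_markers_tsv()]: a long marker tibble; the writer returns
#'   `path` invisibly.
#' @export
read_markers_tsv <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    population = readr::col_character(), individual = readr::col_character(),
    locus = readr::col_character(), allele_1 = readr::col_integer(),
    allele_2 = readr::col_integer()))
  d$allele_1[d$allele_1 == 0L] <- NA_integer_
  d$allele_2[d$allele_2 == 0L] <- NA_integer_
  d
}

#' @rdname read_markers_tsv
#' @inheritParams locus_stats
#' @export
write_markers_tsv <- function(data, path) {
  out <- data %>%
    dplyr::mutate(allele_1 = dplyr::coalesce(.data$allele_1, 0L),
                  allele_2 = dplyr::coalesce(.data$allele_2, 0L))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a genotype matrix TSV
#'
#' Rows are individuals (first column `individual`), remaining columns are
#' markers with cells `H` (heterozygous introgression), `A` (homozygous
#' recurrent) or `-` (missing).
#'
#' @param path Path to the file.
#' @return A long tibble with columns `individual`, `marker`, `genotype`.
#' @export
read_geno_matrix <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  long <- tidyr::pivot_longer(d, -"individual", names_to = "marker",
                              values_to = "genotype")
  long$genotype[long$genotype == "-"] <- NA_character_
  bad <- setdiff(unique(long$genotype), c("H", "A", NA))
  if (length(bad) > 0)
    abort(paste0("unknown genotype codes: ", paste(bad, collapse = ", ")))
  long
}

#' @rdname read_geno_matrix
#' @param geno Long genotype tibble (`individual`, `marker`, `genotype`).
#' @param marker_order Column order for the written matrix.
#' @export
write_geno_matrix <- function(geno, path, marker_order = NULL) {
  wide <- geno %>%
    dplyr::mutate(genotype = dplyr::coalesce(.data$genotype, "-")) %>%
    tidyr::pivot_wider(names_from = "marker", values_from = "genotype")
  if (!is.null(marker_order))
    wide <- dplyr::select(wide, "individual", dplyr::all_of(marker_order))
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read replicate phenotype and inviability-block TSV tables
#'
#' Phenotypes: columns `individual`, `replicate`, `tolerant` (0/1).
#' Blocks: columns `cross_id`, `maternal`, `paternal`, `direction`,
#' `block_size`, `n_inviable` (a `line` column is accepted as an alias for
#' `cross_id`).
#'
#' @param path Path to the file.
#' @return A tibble.
#' @export
read_phenotypes_tsv <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    individual = readr::col_character(), replicate = readr::col_integer(),
    tolerant = readr::col_integer()))
  d$tolerant <- d$tolerant == 1L
  d
}

#' @rdname read_phenotypes_tsv
#' @export
read_blocks_tsv <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols())
  if (!"line" %in% names(d) && "cross_id" %in% names(d))
    d$line <- d$cross_id
  required <- c("line", "block_size", "n_inviable")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0)
    abort(paste0("blocks table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  d
}
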