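#' Export phased genotypes as VCF
#'
#' Writes a minimal phased VCF (GT only, "|" separators).  Physical
#' positions are derived from the genetic map at 1 cM per Mb, 1-based,
#' bumped minimally where rounding would create duplicates.  REF/ALT are
#' arbitrary biallelic codes (A/C); allele 1 of the simulation is the ALT
#' allele.
#'
#' @param pop a \linkS4class{Population}.
#' @param file output path.
#' @param individuals ids to export (default all).
#' @param loci locus rows to export (default all panel loci).
#' @return the file path, invisibly.
#' @export
writePhasedVcf <- function(pop, file, individuals = NULL, loci = NULL) {
  if (is.null(individuals)) individuals <- pop@ped$id
  if (is.null(loci)) loci <- seq_len(nLoci(pop))
  sub <- subsetMap(pop@map, loci)
  h <- haplotypes(pop, individuals = individuals, loci = loci)
  posBp <- as.integer(round(sub@posCm * 1e6)) + 1L
  for (c in unique(sub@chrom)) {
    w <- which(sub@chrom == c)
    p <- posBp[w]
    while (anyDuplicated(p)) p <- p + cumsum(duplicated(p))
    posBp[w] <- p
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%d,length=%d>",
                       seq_along(sub@chromLengths),
                       as.integer(round(sub@chromLengths * 1e6)) + 1L),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT",
                     paste0("ind", individuals)), collapse = "\t"), con)
  n <- length(individuals)
  gt <- matrix(paste(h[, seq(1L, 2L * n, 2L), drop = FALSE],
                     h[, seq(2L, 2L * n, 2L), drop = FALSE], sep = "|"),
               nrow = length(loci))
  body <- paste(sub@chrom, posBp, paste0("site", loci), "A", "C", ".",
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(file)
}

#' Export the pedigree as TSV
#'
#' Columns id, sire, dam, sex, generation with 0 for unknown parents.
#'
#' @param pop a \linkS4class{Population}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writePedigreeTsv <- function(pop, file) {
  write.table(pop@ped, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a relationship matrix as dense text
#'
#' Whitespace-delimited values with a header row of individual ids and
#' '#'-prefixed metadata comments (method tag and construction details).
#'
#' @param rm a \linkS4class{RelationshipMatrix}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeRelMatrix <- function(rm, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# method: %s", methodTag(rm)), con)
  meta <- rm@meta
  scalars <- names(meta)[vapply(meta, function(x)
    is.atomic(x) && length(x) == 1, logical(1))]
  for (nm in scalars)
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  writeLines(paste(indivIds(rm), collapse = " "), con)
  utils::write.table(format(relValues(rm), digits = 10, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a relationship matrix written by \code{\link{writeRelMatrix}}
#'
#' @param file input path.
#' @return a \linkS4class{RelationshipMatrix}.
#' @export
readRelMatrix <- function(file) {
  lines <- readLines(file)
  com <- grepl("^#", lines)
  meta <- list()
  method <- "unknown"
  for (l in lines[com]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key == "method") method <- val else meta[[key]] <- val
  }
  body <- lines[!com]
  ids <- as.integer(strsplit(trimws(body[1]), "\\s+")[[1]])
  v <- do.call(rbind, lapply(body[-1], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  relMat(v, ids, method, meta)
}

#' Export a segment set as TSV
#'
#' Columns indivA, hapA, indivB, hapB, chrom, startCm, endCm, nSnps,
#' mirroring a phased-IBD segment file.
#'
#' @param segset a \linkS4class{SegmentSet}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeSegmentsTsv <- function(segset, file) {
  write.table(segset@segments, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Read a flat key=value scheme configuration file
#'
#' Sections in square brackets ([genome], [base], [trait], [scheme]) with
#' snake_case keys, e.g. \code{n_chrom = 3}; a bare \code{seed = 7} line (or
#' a [seed] section) sets the seed.  Unknown keys are rejected.
#'
#' @param path file path.
#' @return a configuration list as from \code{\link{schemeConfig}}.
#' @export
readConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^[#;]", lines)]
  section <- ""
  vals <- list(genome = list(), base = list(), trait = list(),
               scheme = list())
  keymap <- list(
    genome = c(n_chrom = "nChrom", chrom_cm = "chromCm", n_snp = "nSnp",
               n_neutral = "nNeutral", n_qtl = "nQtl", maf_min = "mafMin",
               mu = "mu", ne = "ne", n_sites = "nSites",
               burnin_generations = "burninGenerations"),
    base = c(n_males = "nMales", n_females = "nFemales",
             n_offspring = "nOffspring",
             n_random_generations = "nRandomGenerations"),
    trait = c(h2 = "h2"),
    scheme = c(scheme = "scheme", d_f = "dF", df = "dF",
               n_select_generations = "nSelectGenerations",
               min_roh_snps = "minRohSnps",
               ref_freq_source = "refFreqSource", fgla_base = "fglaBase"))
  seed <- 1L
  for (l in lines) {
    if (grepl("^\\[", l)) {
      section <- gsub("\\[|\\]", "", l)
      next
    }
    key <- trimws(sub("=.*$", "", l))
    val <- trimws(sub("^[^=]*=", "", l))
    if (key == "seed" || section == "seed") {
      seed <- as.integer(val)
      next
    }
    if (!section %in% names(keymap) || !key %in% names(keymap[[section]]))
      stop(sprintf("unknown configuration key '%s' in section [%s]",
                   key, section))
    num <- suppressWarnings(as.numeric(val))
    vals[[section]][[keymap[[section]][[key]]]] <-
      if (is.na(num)) val else num
  }
  args <- c(vals$scheme,
            list(genome = vals$genome, base = vals$base, trait = vals$trait,
                 seed = seed))
  do.call(schemeConfig, args)
}

#' Write the per-generation diversity report as TSV
#'
#' @param result a \linkS4class{SchemeResult} (or its report data.frame).
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeReportTsv <- function(result, file) {
  rep_ <- if (is(result, "SchemeResult")) schemeReport(result) else result
  write.table(rep_, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
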