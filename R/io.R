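#' Read a replicated phenotype table
#'
#' Long format, header required: columns `genotype`, `rep`, then one column
#' per trait. Separator is inferred from the extension (`.tsv`/`.txt` = tab,
#' otherwise comma).
#'
#' @param path file path.
#' @return a [trait_panel()].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0) stop("empty phenotype file: ", path)
  need <- c("genotype", "rep")
  if (!all(need %in% colnames(df))) {
    stop("phenotype file must have columns 'genotype' and 'rep'; missing: ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  }
  traits <- setdiff(colnames(df), need)
  if (length(traits) == 0) stop("no trait columns found")
  for (tc in traits) {
    bad <- which(!is.na(df[[tc]]) & is.na(suppressWarnings(as.numeric(df[[tc]]))))
    if (length(bad)) {
      stop(sprintf("non-numeric values in trait '%s' at row(s) %s", tc,
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
    df[[tc]] <- as.numeric(df[[tc]])
  }
  message(sprintf("read %d phenotype records, traits: %s", nrow(df),
                  paste(traits, collapse = ", ")))
  trait_panel(df$genotype, df$rep, df[, traits, drop = FALSE])
}

#' Write a trait panel (round-trips with [read_phenotypes()])
#'
#' @param panel a [trait_panel()].
#' @param path output path (.csv or .tsv).
#' @export
write_phenotypes <- function(panel, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(panel), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a marker genotype matrix
#'
#' TSV format: first column genotype id, remaining columns markers, cells in
#' \{0, 1, 2, NA\}. VCF format (requires the `vcfR` package): biallelic SNPs
#' only; the GT field is converted to ALT-allele counts and multiallelic
#' records are skipped with a message.
#'
#' @param path file path.
#' @param format "tsv" or "vcf".
#' @return n x m numeric code matrix with genotype ids as rownames.
#' @export
read_markers <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
    codes <- as.matrix(df[, -1, drop = FALSE])
    mode(codes) <- "numeric"
    rownames(codes) <- as.character(df[[1]])
    if (anyNA(codes)) {
      message(sprintf("missing genotype fraction: %.3f", mean(is.na(codes))))
    }
    return(codes)
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- !grepl(",", vcfR::getALT(v))
  n_multi <- sum(!biallelic)
  if (n_multi > 0) message(sprintf("%d multiallelic record(s) skipped", n_multi))
  v <- v[biallelic, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) sum(a == "1"), numeric(1)))
  }
  codes <- t(apply(gt, 1, count_alt))
  out <- t(codes)                         # genotypes x markers
  colnames(out) <- rownames(gt)
  out
}

#' Write per-cycle selection summaries as response and gains tables
#'
#' Produces the two standard report tables for a recurrent-selection
#' experiment: a response table (columns `cycle`, `index`, `R`, `SCor`,
#' `SR_MSPE`) and a per-trait gains table, each with per-cycle rows followed
#' by an `Average` row per index computed as the arithmetic mean of the
#' cycle rows. Display files round R and gains to 1 decimal and correlations
#' to 3 decimals; `*_full.csv` companions keep full precision.
#'
#' @param summaries data.frame of per-cycle rows as produced by
#'   [empirical_summary()] / [response_and_gains()] (columns `cycle`,
#'   `index`, `R`, `scor`, `sr_mspe`, optional `gain_*`).
#' @param path output stem; writes `<path>_response.csv`, `<path>_gains.csv`
#'   and their `_full` companions.
#' @return invisibly, a list with the two (display-rounded) data.frames.
#' @export
write_summary_tables <- function(summaries, path) {
  if (is.null(summaries) || nrow(summaries) == 0) stop("no summaries to write")
  summaries <- as.data.frame(summaries)
  gain_cols <- grep("^gain_", colnames(summaries), value = TRUE)

  with_avg <- function(df, cols) {
    out <- lapply(split(df, df$index), function(blk) {
      avg <- blk[1, , drop = FALSE]
      avg$cycle <- "Average"
      for (cl in cols) avg[[cl]] <- mean(blk[[cl]])
      blk$cycle <- as.character(blk$cycle)
      rbind(blk, avg)
    })
    do.call(rbind, unname(out))
  }

  resp <- summaries[, c("cycle", "index", "R", "scor", "sr_mspe")]
  colnames(resp) <- c("cycle", "index", "R", "SCor", "SR_MSPE")
  resp_avg <- with_avg(resp, c("R", "SCor", "SR_MSPE"))
  resp_disp <- resp_avg
  resp_disp$R <- round(resp_disp$R, 1)
  resp_disp$SCor <- round(resp_disp$SCor, 3)
  resp_disp$SR_MSPE <- round(resp_disp$SR_MSPE, 1)

  files <- character(0)
  wr <- function(df, suffix) {
    f <- paste0(path, suffix)
    utils::write.table(df, f, sep = ",", row.names = FALSE, quote = FALSE)
    f
  }
  files <- c(files, wr(resp_disp, "_response.csv"), wr(resp_avg, "_response_full.csv"))

  gains_disp <- NULL
  if (length(gain_cols)) {
    gains <- summaries[, c("cycle", "index", gain_cols)]
    gains_avg <- with_avg(gains, gain_cols)
    gains_disp <- gains_avg
    for (cl in gain_cols) gains_disp[[cl]] <- round(gains_disp[[cl]], 1)
    files <- c(files, wr(gains_disp, "_gains.csv"), wr(gains_avg, "_gains_full.csv"))
  }
  invisible(list(response = resp_disp, gains = gains_disp, files = files))
}

#' Write a covariance set as a labeled plain-text bundle
#'
#' Blocks labeled `#P`, `#G`, `#Gamma` (CSV matrix rows with a trait-name
#' header), `#h2` and `#n_reps`; round-trips with
#' [read_covariance_bundle()].
#'
#' @param covs a [covariance_set()].
#' @param path output path.
#' @export
write_covariance_bundle <- function(covs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tn <- covs$traits
  wm <- function(M, label) {
    if (is.null(M)) return()
    writeLines(paste0("#", label), con)
    if (!is.null(tn)) writeLines(paste(tn, collapse = ","), con)
    else writeLines(paste(paste0("T", seq_len(ncol(M))), collapse = ","), con)
    utils::write.table(M, con, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  wm(covs$P, "P"); wm(covs$G, "G"); wm(covs$Gamma, "Gamma")
  if (!is.null(covs$h2)) {
    writeLines("#h2", con)
    writeLines(paste(covs$h2, collapse = ","), con)
  }
  writeLines("#n_reps", con)
  writeLines(format(covs$n_reps), con)
  invisible(path)
}

#' Read a covariance bundle written by [write_covariance_bundle()]
#'
#' @param path bundle path.
#' @return a [covariance_set()].
#' @export
read_covariance_bundle <- function(path) {
  lines <- readLines(path)
  labs <- grep("^#", lines)
  blocks <- list()
  for (i in seq_along(labs)) {
    lab <- sub("^#", "", lines[labs[i]])
    end <- if (i < length(labs)) labs[i + 1] - 1 else length(lines)
    blocks[[lab]] <- lines[(labs[i] + 1):end]
  }
  traits <- NULL
  getm <- function(lab) {
    bl <- blocks[[lab]]
    if (is.null(bl)) return(NULL)
    traits <<- strsplit(bl[1], ",")[[1]]
    M <- do.call(rbind, lapply(bl[-1], function(l) as.numeric(strsplit(l, ",")[[1]])))
    dimnames(M) <- list(traits, traits)
    M
  }
  P <- getm("P"); G <- getm("G"); Gamma <- getm("Gamma")
  h2 <- if (!is.null(blocks$h2)) as.numeric(strsplit(blocks$h2[1], ",")[[1]]) else NULL
  n_reps <- if (!is.null(blocks$n_reps)) as.numeric(blocks$n_reps[1]) else NA_real_
  covariance_set(P = P, G = G, Gamma = Gamma, h2 = h2, n_reps = n_reps, traits = traits)
}

#' Read an economic-weights YAML config
#'
#' Layout: `weights: {w: [...], W: zero|rank1|matrix, matrix: [[...]]}`.
#'
#' @param path YAML file path.
#' @return an [economic_weights()].
#' @export
read_weights_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  wc <- if (!is.null(cfg$weights)) cfg$weights else cfg
  if (is.null(wc$w)) stop("weights config must define 'w'")
  Wspec <- if (is.null(wc$W)) "zero" else wc$W
  if (identical(Wspec, "matrix")) {
    Wspec <- do.call(rbind, lapply(wc$matrix, as.numeric))
  }
  economic_weights(as.numeric(wc$w), Wspec)
}

#' Read a simulator YAML config
#'
#' Layout: a `genome` block with the [genome_config()] fields
#' (`target_genetic_corr` as a list of rows), optional `population`
#' (`n`, `n_reps`) and `selection` (`proportion`) blocks.
#'
#' @param path YAML file path.
#' @return list with `genome` (a [genome_config()]), `n`, `n_reps`,
#'   `proportion`, and the raw config for echoing.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gb <- cfg$genome
  if (is.null(gb)) stop("simulator config must have a 'genome' block")
  R <- do.call(rbind, lapply(gb$target_genetic_corr, as.numeric))
  genome <- genome_config(
    n_chromosomes = gb$n_chromosomes, n_markers = gb$n_markers,
    n_qtl = gb$n_qtl, qtl_per_trait = gb$qtl_per_trait,
    target_genetic_corr = R,
    target_h2 = if (!is.null(gb$target_h2)) gb$target_h2 else NULL,
    chromosome_length_cM = if (!is.null(gb$chromosome_length_cM)) gb$chromosome_length_cM else 100,
    founder_freq = if (!is.null(gb$founder_freq)) gb$founder_freq else 0.5)
  pb <- cfg$population
  ## YAML 1.1 reads a bare `n` key as boolean FALSE; normalize it back
  if (!is.null(pb)) names(pb)[names(pb) %in% c("FALSE", "no")] <- "n"
  list(genome = genome,
       n = as.integer(if (!is.null(pb[["n"]])) pb[["n"]] else 500),
       n_reps = as.integer(if (!is.null(pb[["n_reps"]])) pb[["n_reps"]] else 4),
       proportion = as.numeric(if (!is.null(cfg$selection$proportion)) cfg$selection$proportion else 0.10),
       raw = cfg)
}
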