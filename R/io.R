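# File formats and run configuration: GENEPOP and STRUCTURE genotype files,
# tidy result CSVs, and the YAML/JSON run configuration consumed by the
# command-line interface.

#' Write / read GENEPOP genotype files
#'
#' Canonical dialect written: a title line, one locus name per line, `Pop`
#' separators, individual lines `name ,  aaabbb aaabbb ...` with 3-digit
#' allele codes and `000` for missing.  The reader is tolerant: it accepts
#' comma-separated locus names on one line, 2- or 3-digit codes, and any
#' case of `pop`.  Round-trips are lossless for allele IDs 1-999.
#'
#' @param g a [genotype_matrix].
#' @param path file path.
#' @param title GENEPOP title line.
#' @return `write_genepop()` returns `path` invisibly; `read_genepop()`
#'   returns a [genotype_matrix] with labels `pop1`, `pop2`, ... per block.
#' @export
write_genepop <- function(g, path, title = "driftlag export") {
  stopifnot(inherits(g, "genotype_matrix"))
  if (any(g$a1 > 999L, na.rm = TRUE) || any(g$a2 > 999L, na.rm = TRUE))
    stop("GENEPOP allele codes are limited to 999")
  fmt <- function(x) ifelse(is.na(x), "000", sprintf("%03d", x))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(g$loci, con)
  for (p in levels(g$pop)) {
    writeLines("Pop", con)
    idx <- which(g$pop == p)
    for (i in idx) {
      geno <- paste0(fmt(g$a1[i, ]), fmt(g$a2[i, ]))
      writeLines(paste0(p, "_", i, " ,  ", paste(geno, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' @rdname write_genepop
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("not a GENEPOP file: too few lines")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L)
    stop("not a GENEPOP file: no Pop separator after the locus list")
  loci_lines <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(loci_lines, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  a1 <- NULL; a2 <- NULL; pop <- character(0); block <- 0L
  for (ln in seq(first_pop, length(lines))) {
    if (is_pop[ln]) { block <- block + 1L; next }
    line <- lines[ln]
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L)
      stop("GENEPOP parse error at line ", ln, ": missing ',' separator")
    genos <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(genos) != L)
      stop("GENEPOP parse error at line ", ln, ": expected ", L,
           " genotypes, found ", length(genos))
    w <- unique(nchar(genos))
    if (length(w) != 1L || !w %in% c(4L, 6L))
      stop("GENEPOP parse error at line ", ln,
           ": allele codes must be uniformly 2- or 3-digit")
    half <- w / 2L
    x1 <- as.integer(substr(genos, 1L, half))
    x2 <- as.integer(substr(genos, half + 1L, w))
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    miss <- is.na(x1) | is.na(x2)
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1 <- rbind(a1, x1); a2 <- rbind(a2, x2)
    pop <- c(pop, paste0("pop", block))
  }
  if (is.null(a1)) stop("GENEPOP file contains no individuals")
  genotype_matrix(a1, a2, pop, loci)
}

#' Write / read STRUCTURE-format genotype files
#'
#' Two rows per individual (one per allele copy); columns are individual
#' name, population index, then one integer allele code per locus, with -9
#' for missing.  A header row carries the locus names.
#'
#' @inheritParams write_genepop
#' @return `write_structure()` returns `path` invisibly; `read_structure()`
#'   a [genotype_matrix].
#' @export
write_structure <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(g$loci, collapse = "\t"), con)
  if (nrow(g$a1) == 0L) {
    warning("writing a header-only STRUCTURE file: no individuals")
    return(invisible(path))
  }
  fmt <- function(x) ifelse(is.na(x), -9L, x)
  for (i in seq_len(nrow(g$a1))) {
    id <- paste0(g$pop[i], "_", i)
    pi <- as.integer(g$pop[i])
    writeLines(paste(c(id, pi, fmt(g$a1[i, ])), collapse = "\t"), con)
    writeLines(paste(c(id, pi, fmt(g$a2[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  loci <- strsplit(lines[1], "\t")[[1]]
  body <- lines[-1]
  if (length(body) %% 2L != 0L)
    stop("STRUCTURE file must have two rows per individual")
  parse <- function(ln) strsplit(ln, "\t")[[1]]
  n <- length(body) / 2L
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  pop <- character(n)
  for (i in seq_len(n)) {
    r1 <- parse(body[2 * i - 1L]); r2 <- parse(body[2 * i])
    if (r1[1] != r2[1])
      stop("row pair mismatch at individual ", i, ": ", r1[1], " vs ", r2[1])
    pop[i] <- r1[2]
    x1 <- as.integer(r1[-(1:2)]); x2 <- as.integer(r2[-(1:2)])
    x1[x1 == -9L] <- NA_integer_; x2[x2 == -9L] <- NA_integer_
    miss <- is.na(x1) | is.na(x2)
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[i, ] <- x1; a2[i, ] <- x2
  }
  genotype_matrix(a1, a2, paste0("pop", pop), loci)
}

#' Estimate allele frequencies from a genotype matrix by counting
#'
#' Helper for founding simulations from external (e.g. GENEPOP) data:
#' pools all individuals and counts alleles per locus, re-indexing allele
#' IDs to consecutive `1..k`.
#'
#' @param g a [genotype_matrix].
#' @return an [allele_freqs] object.
#' @export
count_allele_freqs <- function(g) {
  loci <- lapply(seq_len(ncol(g$a1)), function(l) {
    x <- stats::na.omit(c(g$a1[, l], g$a2[, l]))
    if (length(x) == 0L) stop("locus ", g$loci[l], " entirely missing")
    as.numeric(table(x) / length(x))
  })
  names(loci) <- g$loci
  allele_freqs(loci)
}

run_config_defaults <- function() {
  list(n_source = 1000L, n_isolated = 50L, annual_survival = 0.96,
       max_age = 62L, maturity_age = 3L, burn_in = 75L, horizon = 400L,
       n_replicates = 100L, subsample_size = 50L, clustering_interval = 25L,
       n_isolated_grid = NULL, max_age_grid = NULL,
       k_max = 3L, runs_per_k = 5L, mcmc = 100000L, burnin = 100000L,
       n_pcs = NULL, stat_years = NULL, clustering_years = NULL,
       do_clustering = TRUE, founder_csv = NULL, out_dir = "driftlag-out",
       master_seed = 1L, workers = 1L)
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' The configuration mirrors [sim_params()] plus grid lists
#' (`n_isolated_grid`, `max_age_grid`), analysis knobs (`k_max`,
#' `runs_per_k`, `mcmc`, `burnin`, `n_pcs`, `stat_years`,
#' `clustering_years`, `do_clustering`), `founder_csv`, `out_dir`,
#' `master_seed` and `workers`.  Unknown keys are rejected before any
#' simulation starts.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("config must be a .yaml/.yml or .json file")
  defaults <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg)
  # validate the sim_params subset now, before any work happens
  do.call(sim_params, out[names(formals(sim_params))])
  structure(out, class = "run_config")
}

#' Configuration and parameters resolved into [sim_params]/[analysis_config]
#' @param cfg a `run_config` list.
#' @return list with elements `params`, `analysis`, `freqs`.
#' @export
resolve_run_config <- function(cfg) {
  params <- do.call(sim_params, unclass(cfg)[names(formals(sim_params))])
  analysis <- analysis_config(stat_years = cfg$stat_years,
                              clustering_years = cfg$clustering_years,
                              do_clustering = cfg$do_clustering,
                              k_max = cfg$k_max, runs = cfg$runs_per_k,
                              mcmc = cfg$mcmc, burnin = cfg$burnin,
                              n_pcs = cfg$n_pcs)
  freqs <- if (!is.null(cfg$founder_csv)) read_allele_freqs(cfg$founder_csv)
           else founder_profile()
  list(params = params, analysis = analysis, freqs = freqs)
}

#' Write a grid result to tidy CSV files
#'
#' Emits `grid_summary.csv`, `traces.csv` (long format: replicate seed,
#' year, statistic, value) and `detection_frequency.csv` into `dir`.  Every
#' file starts with comment lines recording the package version and master
#' seed so outputs are attributable to a configuration.
#'
#' @param res a `grid_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_grid_csvs <- function(res, dir) {
  stopifnot(inherits(res, "grid_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("# driftlag %s",
                   as.character(utils::packageVersion("driftlag"))),
           sprintf("# master_seed %d", res$master_seed))
  emit <- function(df, name) {
    p <- file.path(dir, name)
    writeLines(hdr, p)
    suppressWarnings(utils::write.table(df, p, append = TRUE, sep = ",",
                                        row.names = FALSE, quote = FALSE))
  }
  emit(res$summary, "grid_summary.csv")
  if (!is.null(res$detection) && nrow(res$detection))
    emit(res$detection, "detection_frequency.csv")
  traces_long <- do.call(rbind, lapply(seq_len(nrow(res$sets)), function(si) {
    do.call(rbind, lapply(res$traces[[si]], function(tr) {
      y <- tr$yearly
      long <- do.call(rbind, lapply(
        c("he_source", "he_isolated", "theta", "dapc_misassignment"),
        function(s) data.frame(year = y$year, statistic = s,
                               value = y[[s]])))
      long <- long[!is.na(long$value), ]
      if (nrow(tr$clustering))
        long <- rbind(long, data.frame(year = tr$clustering$year,
                                       statistic = "best_k",
                                       value = tr$clustering$best_k))
      cbind(set_id = res$sets$set_id[si],
            n_isolated = res$sets$n_isolated[si],
            max_age = res$sets$max_age[si],
            replicate_seed = tr$seed, long)
    }))
  }))
  emit(traces_long, "traces.csv")
  invisible(dir)
}
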