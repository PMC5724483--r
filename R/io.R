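# Plain-text file formats: per-taxon SFS files, the simulation-directory
# layout, and single-file reference tables.  All numeric output uses 6
# significant digits, stated in each header.

fmt6 <- function(x) formatC(x, digits = 6, format = "g")

#' Write / read a folded SFS file
#'
#' One taxon per file: a header line `#n_samples=<k> n_snps=<m>` followed by
#' whitespace-separated proportions over the minor-allele classes.
#'
#' @param sfs A [folded_sfs()].
#' @param path File path.
#' @return `read_sfs()` returns a [folded_sfs()]; `write_sfs()` returns
#'   `path` invisibly.
#' @export
write_sfs <- function(sfs, path) {
  stopifnot(inherits(sfs, "folded_sfs"))
  writeLines(c(sprintf("#n_samples=%d n_snps=%d", sfs$n_samples,
                       sfs$n_snps),
               paste(fmt6(sfs$proportions), collapse = " ")), path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1L]
  if (!grepl("^#n_samples=", hdr))
    stop("not a folded SFS file (missing header): ", path)
  n_samples <- as.integer(sub(".*n_samples=(\\d+).*", "\\1", hdr))
  n_snps <- as.integer(sub(".*n_snps=(\\d+).*", "\\1", hdr))
  props <- scan(text = lines[2L], quiet = TRUE)
  folded_sfs(props / sum(props), n_samples, n_snps)
}

#' Import a dadi-style single-population folded SFS
#'
#' Reads the dadi text dialect: a first line giving the number of entries
#' (n_samples + 1) and the word `folded`, a line of per-class values
#' indexed 0..n_samples, and an optional mask line.  The monomorphic
#' class(es) and any masked or empty upper classes are dropped, leaving the
#' polymorphic folded classes 1..floor(n/2), normalised to proportions.
#'
#' @param path File path.
#' @return A [folded_sfs()].
#' @export
read_dadi_sfs <- function(path) {
  lines <- grep("^\\s*$", readLines(path), value = TRUE, invert = TRUE)
  hdr <- scan(text = lines[1L], what = "", quiet = TRUE)
  n_entries <- as.integer(hdr[1L])
  if (!any(tolower(hdr) == "folded"))
    stop("only the folded dadi dialect is supported")
  vals <- scan(text = lines[2L], quiet = TRUE)
  if (length(vals) != n_entries)
    stop("dadi SFS has ", length(vals), " entries, header promises ",
         n_entries)
  n_samples <- n_entries - 1L
  cls <- vals[1L + seq_len(n_samples %/% 2L)]  # classes 1..floor(n/2)
  folded_sfs(cls / sum(cls), n_samples, round(sum(cls)))
}

sim_dir_files <- function(n_taxa) {
  list(taxa = sprintf("taxon_%02d.txt", seq_len(n_taxa)),
       quantities = c(Psi = "hyperparam_Psi.txt", psi = "hyperparam_psi.txt",
                      sigma = "hyperparam_sigma.txt",
                      zeta_T = "hyperparam_zeta_T.txt",
                      omega_tau = "summary_omega_tau.txt",
                      e_tau = "summary_e_tau.txt",
                      tau = "param_tau.txt", epsilon = "param_epsilon.txt",
                      N = "param_N.txt"))
}

#' Write a simulation batch to a plain-text directory
#'
#' Writes one file per taxon (one row of per-taxon summary values per
#' simulation) plus one file per requested hyperparameter, parameter vector
#' or parameter summary, so the total file count is the number of taxa plus
#' the number of requested quantities.  Appending to an existing directory
#' resumes a run; mismatched row counts across files (a partial row from an
#' interrupted run) are detected and refused.
#'
#' @param batch A [simulate_codemo()] result.
#' @param dir Output directory (created if needed).
#' @param output Quantities to write alongside the per-taxon files; any of
#'   `"Psi"`, `"psi"`, `"sigma"`, `"zeta_T"`, `"omega_tau"`, `"e_tau"`,
#'   `"tau"`, `"epsilon"`, `"N"`.
#' @param append Append to an existing directory instead of refusing to
#'   overwrite.
#' @return `dir`, invisibly.
#' @export
write_sim_dir <- function(batch, dir,
                          output = c("Psi", "psi", "sigma", "zeta_T",
                                     "omega_tau", "e_tau", "tau",
                                     "epsilon", "N"),
                          append = FALSE) {
  stopifnot(inherits(batch, "sim_batch"))
  output <- match.arg(output, several.ok = TRUE)
  files <- sim_dir_files(batch$n_taxa)
  existing <- dir.exists(dir) && length(list.files(dir)) > 0L
  if (existing && !append)
    stop("directory not empty (use append = TRUE to resume): ", dir)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (existing) check_sim_dir_rows(dir, batch$n_taxa)
  hdr <- sprintf(
    "# codemo sim dir | mode=%s n_taxa=%d n_samples=%d n_genealogies=%s seed=%s offset=%s | 6 significant digits",
    batch$mode, batch$n_taxa, batch$n_samples,
    batch$provenance$n_genealogies %||% "NA",
    batch$provenance$seed %||% "NA", batch$provenance$sim_offset %||% 0)
  put <- function(file, m) {
    path <- file.path(dir, file)
    fresh <- !file.exists(path)
    con <- file(path, open = "a")
    on.exit(close(con))
    if (fresh) writeLines(hdr, con)
    write.table(matrix(fmt6(as.matrix(m)), nrow = nrow(as.matrix(m))),
                con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  for (tx in seq_len(batch$n_taxa))
    put(files$taxa[tx], batch$taxon_stats[, tx, ])
  src <- list(Psi = batch$labels$Psi, psi = batch$labels$psi,
              sigma = batch$labels$sigma, zeta_T = batch$labels$zeta_T,
              omega_tau = batch$param_summaries$omega_tau,
              e_tau = batch$param_summaries$e_tau,
              tau = batch$tau, epsilon = batch$epsilon, N = batch$n_e)
  for (q in output) put(files$quantities[[q]], src[[q]])
  invisible(dir)
}

check_sim_dir_rows <- function(dir, n_taxa = NULL) {
  fs <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  counts <- vapply(fs, function(f) length(readLines(f)) - 1L, 0L)
  if (length(unique(counts)) > 1L)
    stop("partial rows detected on resume: file row counts differ (",
         paste(basename(fs), counts, sep = "=", collapse = ", "), ")")
  unname(counts[1L])
}

#' Read one or more simulation directories back into a batch
#'
#' @param dirs Character vector of directories written by
#'   [write_sim_dir()] (e.g. shards from parallel runs); rows are
#'   concatenated in the order given.
#' @return A `"sim_batch"`.
#' @export
read_sim_dir <- function(dirs) {
  batches <- lapply(dirs, read_one_sim_dir)
  if (length(batches) == 1L) batches[[1L]] else bind_sim_batches(batches)
}

read_one_sim_dir <- function(dir) {
  taxa_files <- sort(list.files(dir, pattern = "^taxon_\\d+\\.txt$",
                                full.names = TRUE))
  if (!length(taxa_files)) stop("no taxon files found in ", dir)
  hdr <- readLines(taxa_files[1L], n = 1L)
  meta <- function(key, default = NA) {
    m <- regmatches(hdr, regexec(paste0(key, "=([^ ]+)"), hdr))[[1L]]
    if (length(m) < 2L) default else m[2L]
  }
  mode <- meta("mode", "asfs")
  n_samples <- as.integer(meta("n_samples", "0"))
  n_taxa <- length(taxa_files)
  read_mat <- function(path)
    as.matrix(read.table(path, skip = 1L, header = FALSE))
  stats <- lapply(taxa_files, read_mat)
  total <- nrow(stats[[1L]])
  n_cols <- ncol(stats[[1L]])
  arr <- array(NA_real_, c(total, n_taxa, n_cols))
  for (tx in seq_len(n_taxa)) {
    if (nrow(stats[[tx]]) != total)
      stop("row-count mismatch across taxon files in ", dir)
    arr[, tx, ] <- stats[[tx]]
  }
  files <- sim_dir_files(n_taxa)
  grab <- function(q, ncol_expect = 1L) {
    p <- file.path(dir, files$quantities[[q]])
    if (!file.exists(p)) return(NULL)
    m <- read_mat(p)
    if (nrow(m) != total)
      stop("row-count mismatch for ", basename(p), " in ", dir)
    m
  }
  lab <- function(q, fallback) {
    m <- grab(q)
    if (is.null(m)) rep(fallback, total) else as.vector(m)
  }
  labels <- data.frame(psi = as.integer(lab("psi", NA)),
                       sigma = as.integer(lab("sigma", NA)),
                       Psi = as.integer(lab("Psi", NA)),
                       zeta_T = lab("zeta_T", NA))
  param_summaries <- data.frame(omega_tau = lab("omega_tau", NA),
                                e_tau = lab("e_tau", NA))
  mat_or_na <- function(q) {
    m <- grab(q)
    if (is.null(m)) matrix(NA_real_, total, n_taxa) else m
  }
  structure(list(mode = mode, n_taxa = n_taxa, n_samples = n_samples,
                 n_stat_cols = n_cols, taxon_stats = arr, labels = labels,
                 param_summaries = param_summaries,
                 tau = mat_or_na("tau"), epsilon = mat_or_na("epsilon"),
                 n_e = mat_or_na("N"),
                 provenance = list(dir = dir, header = hdr)),
            class = "sim_batch")
}

#' Write / read a reference table as a single text file
#'
#' One row per simulation: the summary-statistic vector followed by the
#' labels (psi, sigma, Psi, zeta_T) and parameter summaries (omega_tau,
#' e_tau), with a provenance header.
#'
#' @param table A `ref_table`.
#' @param path File path.
#' @return `read_ref_table()` returns a `ref_table` (without per-taxon
#'   parameter matrices); `write_ref_table()` returns `path` invisibly.
#' @export
write_ref_table <- function(table, path) {
  stopifnot(inherits(table, "ref_table"))
  df <- data.frame(table$summaries, table$labels, table$param_summaries,
                   check.names = FALSE)
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# codemo ref_table | mode=%s n_taxa=%d n_samples=%d n_stats=%d | 6 significant digits",
    table$mode, table$n_taxa, table$n_samples, ncol(table$summaries)), con)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt6)
  write.table(df, con, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ref_table
#' @export
read_ref_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  df <- read.table(path, skip = 1L, header = TRUE, check.names = FALSE)
  meta <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=([^ ]+)"), hdr))[[1L]]
    if (length(m) < 2L) NA else m[2L]
  }
  n_stats <- as.integer(meta("n_stats"))
  lab_cols <- c("psi", "sigma", "Psi", "zeta_T")
  sum_cols <- c("omega_tau", "e_tau")
  structure(list(
    summaries = as.matrix(df[, seq_len(n_stats), drop = FALSE]),
    labels = df[, lab_cols],
    param_summaries = df[, sum_cols],
    tau = NULL, epsilon = NULL, n_e = NULL,
    mode = meta("mode"), n_taxa = as.integer(meta("n_taxa")),
    n_samples = as.integer(meta("n_samples")),
    provenance = list(path = path, header = hdr)),
    class = "ref_table")
}
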