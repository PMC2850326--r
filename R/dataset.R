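# FlyEx-style quantitative expression data: per-nucleus, per-time-class
# protein concentrations plus the Bcd input profile.
#
# On-disk format is tab-delimited text with '#' comment headers and
# columns: time_class, nucleus_index, ap_position_percent, bcd, then one
# column per gene.  The earliest time class doubles as the initial
# condition of the simulation and is excluded from the least-squares sum.

#' Construct an expression data set
#'
#' @param obs Data frame with columns `time_class`, `nucleus_index`,
#'   `gene`, `conc` (long format). Must include the earliest time class,
#'   which is used as the initial condition.
#' @param bcd_profiles Named list of per-epoch Bcd vectors; names are the
#'   division counts ("0", "1", ...).
#' @param genes Character vector fixing gene order.
#' @param initial_n_div Division count at the earliest time class.
#' @return An object of class `expression_dataset` with per-gene maxima
#'   (`gene_maxima`), the maximum Bcd level (`bcd_max`) and the initial
#'   state.
#' @export
expression_dataset <- function(obs, bcd_profiles, genes,
                               initial_n_div = 0L) {
  req <- c("time_class", "nucleus_index", "gene", "conc")
  if (!all(req %in% names(obs)))
    stop("obs must have columns ", paste(req, collapse = ", "))
  if (any(obs$conc < 0)) stop("concentrations must be non-negative")
  if (!all(obs$gene %in% genes))
    stop("obs contains genes not listed in 'genes'")
  key <- paste(obs$time_class, obs$gene, obs$nucleus_index)
  if (anyDuplicated(key))
    stop("duplicate (time_class, gene, nucleus) observation")
  times <- sort(unique(obs$time_class))
  # nucleus counts per time class determine the division epoch
  n_nuc <- vapply(times, function(t)
    max(obs$nucleus_index[obs$time_class == t]), numeric(1))
  n0 <- n_nuc[1]
  epoch <- log2(n_nuc / n0)
  if (any(abs(epoch - round(epoch)) > 1e-9))
    stop("nucleus counts across time classes must be related by doublings")
  epoch <- as.integer(round(epoch)) + as.integer(initial_n_div)
  need <- as.character(sort(unique(epoch)))
  if (!all(need %in% names(bcd_profiles)))
    stop("missing Bcd profile for epoch(s) ",
         paste(setdiff(need, names(bcd_profiles)), collapse = ", "))
  for (e in names(bcd_profiles)) {
    expect_n <- n0 * 2^(as.integer(e) - as.integer(initial_n_div))
    if (length(bcd_profiles[[e]]) != expect_n)
      stop("Bcd profile for epoch ", e, " has ",
           length(bcd_profiles[[e]]), " values; expected ", expect_n)
  }
  gene_maxima <- vapply(genes, function(g)
    max(obs$conc[obs$gene == g]), numeric(1))
  # initial condition from the earliest time class
  init <- .obs_matrix(obs, times[1], genes)
  if (any(is.na(init)))
    stop("earliest time class must be fully observed (initial condition)")
  structure(list(
    obs = obs[order(obs$time_class, obs$gene, obs$nucleus_index), ,
              drop = FALSE],
    genes = genes,
    times = times,
    epoch_by_time = stats::setNames(epoch, times),
    bcd_profiles = bcd_profiles,
    gene_maxima = gene_maxima,
    bcd_max = max(unlist(bcd_profiles)),
    initial = embryo_state(init, initial_n_div,
                           bcd_profiles[[as.character(initial_n_div)]],
                           times[1])),
    class = "expression_dataset")
}

# observations of one time class as a nuclei x genes matrix (NA = missing)
.obs_matrix <- function(obs, time_class, genes) {
  sub <- obs[obs$time_class == time_class, , drop = FALSE]
  N <- max(sub$nucleus_index)
  mat <- matrix(NA_real_, N, length(genes))
  gi <- match(sub$gene, genes)
  mat[cbind(sub$nucleus_index, gi)] <- sub$conc
  mat
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression data set:", length(x$genes), "genes (",
      paste(x$genes, collapse = ", "), ") at time classes",
      paste(x$times, collapse = ", "), "min\n")
  cat("  ", nrow(x$obs), "observations;",
      nrow(x$initial$conc), "nuclei at the initial time class\n")
  invisible(x)
}

#' Write an expression data set as FlyEx-style TSV
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path.
#' @param ap_range A-P window (percent egg length) used for the position
#'   column.
#' @param meta Optional named character vector of `#` header lines.
#' @export
write_expression_table <- function(dataset, path, ap_range = c(35, 92),
                                   meta = NULL) {
  blocks <- lapply(dataset$times, function(t) {
    mat <- .obs_matrix(dataset$obs, t, dataset$genes)
    epoch <- dataset$epoch_by_time[[as.character(t)]]
    bcd <- dataset$bcd_profiles[[as.character(epoch)]]
    df <- data.frame(time_class = t, nucleus_index = seq_len(nrow(mat)),
                     ap_position_percent = ap_positions(nrow(mat), ap_range),
                     bcd = bcd)
    conc <- as.data.frame(mat)
    names(conc) <- dataset$genes
    cbind(df, conc)
  })
  .write_tsv(do.call(rbind, blocks), path, meta)
}

#' Read a FlyEx-style expression TSV
#'
#' Strictly validates the header, non-negativity and key uniqueness;
#' malformed rows are reported with their line number.
#'
#' @param path File path.
#' @param initial_n_div Division count at the earliest time class.
#' @return An [expression_dataset()].
#' @export
read_expression_table <- function(path, initial_n_div = 0L) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#")
  if (!any(body)) stop("no data rows in ", path)
  first <- which(body)[1]
  header <- strsplit(lines[first], "\t", fixed = TRUE)[[1]]
  fixed_cols <- c("time_class", "nucleus_index", "ap_position_percent",
                  "bcd")
  if (!identical(header[seq_along(fixed_cols)], fixed_cols))
    stop("invalid header; expected columns ",
         paste(fixed_cols, collapse = ", "), ", <genes...>")
  genes <- header[-seq_along(fixed_cols)]
  if (length(genes) < 1) stop("no gene columns in header")
  df <- tryCatch(
    utils::read.table(text = lines[body][-1], sep = "\t",
                      col.names = header, colClasses = "numeric"),
    error = function(e) stop("malformed table in ", path, ": ",
                             conditionMessage(e)))
  # per-row validation with original line numbers
  line_no <- which(body)[-1]
  bad <- which(!stats::complete.cases(df[fixed_cols]))
  if (length(bad))
    stop("malformed row at line ", line_no[bad[1]], " of ", path)
  neg <- which(apply(df[genes] < 0, 1, any) | df$bcd < 0)
  if (length(neg))
    stop("negative concentration at line ", line_no[neg[1]], " of ", path)

  obs <- do.call(rbind, lapply(genes, function(g) {
    keep <- !is.na(df[[g]])
    data.frame(time_class = df$time_class[keep],
               nucleus_index = df$nucleus_index[keep],
               gene = g, conc = df[[g]][keep],
               stringsAsFactors = FALSE)
  }))
  # reconstruct per-epoch Bcd profiles from the bcd column
  times <- sort(unique(df$time_class))
  n0 <- max(df$nucleus_index[df$time_class == times[1]])
  bcd_profiles <- list()
  for (t in times) {
    sub <- df[df$time_class == t, , drop = FALSE]
    sub <- sub[order(sub$nucleus_index), , drop = FALSE]
    epoch <- log2(nrow(sub) / n0)
    if (abs(epoch - round(epoch)) > 1e-9)
      stop("nucleus counts across time classes must be related by doublings")
    e <- as.character(as.integer(round(epoch)) + as.integer(initial_n_div))
    if (is.null(bcd_profiles[[e]])) {
      bcd_profiles[[e]] <- sub$bcd
    } else if (any(abs(bcd_profiles[[e]] - sub$bcd) > 1e-9)) {
      stop("inconsistent Bcd profiles within division epoch ", e)
    }
  }
  expression_dataset(obs, bcd_profiles, genes, initial_n_div)
}
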