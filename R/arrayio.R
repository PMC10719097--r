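# Reading and writing: GenomeStudio-final-report-style quartet tables in,
# BED + JSON call files out.  Internal coordinates are 1-based inclusive
# (array-manifest convention); BED output is 0-based half-open.

.FR_FIXED <- c("SNP Name", "Chr", "Position")
.FR_SUFFIX <- c(gtype = "GType", baf = "B Allele Freq", logr = "Log R Ratio")

#' Write a quartet as a final-report-style table
#'
#' Tab-separated table with columns `SNP Name`, `Chr`, `Position` and, per
#' sample, `<name>.GType`, `<name>.B Allele Freq`, `<name>.Log R Ratio`.
#'
#' @param quartet a `"trio_quartet"`.
#' @param path output path.
#' @param samples sample column names, in the order mother, father, CV, EM.
#' @return `path`, invisibly.
#' @export
write_final_report <- function(quartet, path,
                               samples = c(mother = "Mother",
                                           father = "Father",
                                           cv = "CV", em = "EM")) {
  pm <- quartet$probe_map
  tab <- data.frame(pm$probe_id, pm$chromosome, pm$position,
                    stringsAsFactors = FALSE)
  hdr <- .FR_FIXED
  roles <- c("mother", "father", "cv", "em")
  for (r in roles) {
    s <- quartet[[r]]
    if (is.null(s)) next
    tab <- cbind(tab, s$gtype, round(s$baf, 4), round(s$logr, 4))
    hdr <- c(hdr, paste0(samples[[r]], ".", .FR_SUFFIX))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a final-report-style quartet table
#'
#' Expects the columns written by [write_final_report()].  The EM sample is
#' optional; mother, father and CV (the phasing seed) are mandatory.  Rows
#' whose position cannot be parsed are dropped with a message; duplicated
#' probe ids or a missing mandatory column raise an error naming the
#' offender.  Population B-allele frequencies are not part of final
#' reports; the returned probe map carries 0.5.
#'
#' @param path input path.
#' @param samples sample column names, as in [write_final_report()].
#' @return a `"trio_quartet"`.
#' @export
read_final_report <- function(path,
                              samples = c(mother = "Mother",
                                          father = "Father",
                                          cv = "CV", em = "EM")) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (cn in .FR_FIXED)
    if (!cn %in% names(tab)) stop("missing mandatory column: '", cn, "'")
  get_sample <- function(name, mandatory) {
    cols <- paste0(name, ".", .FR_SUFFIX)
    present <- cols %in% names(tab)
    if (!any(present) && !mandatory) return(NULL)
    if (!all(present))
      stop("missing mandatory column: '", cols[!present][1], "'")
    list(gtype = as.character(tab[[cols[1]]]),
         baf = as.numeric(tab[[cols[2]]]),
         logr = as.numeric(tab[[cols[3]]]))
  }
  pos <- suppressWarnings(as.numeric(tab[["Position"]]))
  bad <- is.na(pos)
  if (any(bad)) {
    message("dropped ", sum(bad), " row(s) with unparseable position")
    tab <- tab[!bad, , drop = FALSE]; pos <- pos[!bad]
  }
  if (anyDuplicated(tab[["SNP Name"]]))
    stop("duplicated probe id(s) in final report")
  ord <- order(match(normalize_chrom(tab[["Chr"]]), .CHROMS), pos)
  tab <- tab[ord, , drop = FALSE]; pos <- pos[ord]
  pm <- probe_map(tab[["SNP Name"]], tab[["Chr"]], pos,
                  rep(0.5, nrow(tab)))
  arr <- function(role, mandatory) {
    s <- get_sample(samples[[role]], mandatory)
    if (is.null(s)) return(NULL)
    new_sample_array(s$gtype, s$baf, s$logr,
                     switch(role, mother = "mother", father = "father",
                            cv = "CV", em = "EM"))
  }
  new_trio_quartet(pm,
                   mother = arr("mother", TRUE),
                   father = arr("father", TRUE),
                   cv = arr("cv", TRUE),
                   em = arr("em", FALSE))
}

#' Write a quartet and its ground truth to a directory
#'
#' Writes `<prefix>.txt` (final report) and, when the quartet carries
#' simulated ground truth, `<prefix>_truth.json` with the aberration spec
#' and noise settings.
#'
#' @param quartet a `"trio_quartet"`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return the final-report path, invisibly.
#' @export
write_quartet <- function(quartet, dir, prefix = "quartet") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fr <- file.path(dir, paste0(prefix, ".txt"))
  write_final_report(quartet, fr)
  if (!is.null(quartet$truth)) {
    tr <- quartet$truth
    keep <- list(aberration = unclass(tr$aberration),
                 noise = unclass(tr$noise), seed = tr$seed)
    jsonlite::write_json(keep, file.path(dir, paste0(prefix, "_truth.json")),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(fr)
}

#' Write aberration calls as BED + JSON
#'
#' `<path>.bed` holds the intervals in 0-based half-open coordinates
#' (internal 1-based inclusive start becomes `start - 1`; the inclusive end
#' is already the half-open end); `<path>.json` carries the full
#' annotations.  Calls identical in tissue, state, origin and copy number
#' whose intervals overlap are merged with a message.
#'
#' @param calls an `"aberration_calls"` data frame.
#' @param path output path stem (without extension).
#' @return named character vector with the two paths, invisibly.
#' @export
write_calls <- function(calls, path) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) > 1) {
    key <- paste(calls$tissue, calls$chromosome, calls$copy_state,
                 calls$parental_origin, calls$copy_number)
    merged <- calls[0, , drop = FALSE]
    for (k in unique(key)) {
      sub <- calls[key == k, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      i <- 1
      while (i <= nrow(sub)) {
        j <- i
        while (j < nrow(sub) && sub$start[j + 1] <= sub$end[j]) {
          sub$end[j + 1] <- max(sub$end[j + 1], sub$end[j]); j <- j + 1
        }
        row <- sub[j, , drop = FALSE]; row$start <- sub$start[i]
        merged <- rbind(merged, row)
        if (j > i) message("merged ", j - i + 1, " overlapping identical call(s)")
        i <- j + 1
      }
    }
    calls <- merged[order(match(merged$chromosome, .CHROMS), merged$start), ,
                    drop = FALSE]
  }
  bed <- paste0(path, ".bed"); json <- paste0(path, ".json")
  con <- file(bed, "w")
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
  if (nrow(calls) > 0) {
    bedtab <- data.frame(calls$chromosome,
                         format(calls$start - 1, scientific = FALSE, trim = TRUE),
                         format(calls$end, scientific = FALSE, trim = TRUE),
                         paste(calls$tissue, calls$copy_state,
                               calls$parental_origin,
                               calls$segregational_origin, sep = ":"),
                         round(1000 * calls$mosaic_fraction),
                         ".", stringsAsFactors = FALSE)
    utils::write.table(bedtab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  close(con)
  jsonlite::write_json(list(n_calls = nrow(calls), calls = calls), json,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(bed = bed, json = json))
}

#' Read aberration calls back from a JSON call file
#'
#' @param path path to the `.json` file written by [write_calls()].
#' @return an `"aberration_calls"` data frame.
#' @export
read_calls <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calls <- x$calls
  if (length(calls) == 0 || is.null(nrow(calls)))
    calls <- data.frame(tissue = character(), chromosome = character(),
                        start = numeric(), end = numeric(),
                        size_class = character(), copy_state = character(),
                        copy_number = integer(),
                        parental_origin = character(),
                        segregational_origin = character(),
                        mosaic_fraction = numeric(), d_pat = numeric(),
                        d_mat = numeric(), mean_logr = numeric(),
                        stringsAsFactors = FALSE)
  structure(calls, class = c("aberration_calls", "data.frame"))
}
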