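.delimFor <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read case volume tables from CSV/TSV
#'
#' Long format with header columns \code{case_id}, \code{age},
#' \code{structure_id}, \code{volume_mm3}; the delimiter is taken from the
#' extension (.csv comma, otherwise tab).  Duplicate (case, structure) rows,
#' negative volumes, unparseable ages and inconsistent per-case ages are
#' hard errors naming the offending data row.
#'
#' @param path file path.
#' @return list of base-level [VolumeTable-class] objects, one per case, in
#'   order of first appearance.
#' @export
readVolumeTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .delimFor(path),
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("case_id", "age", "structure_id", "volume_mm3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("volume table is missing column(s): ", paste(miss, collapse = ", "))
  age <- suppressWarnings(as.numeric(df$age))
  if (anyNA(age) || any(age <= 0))
    stop("unparseable or non-positive age at data row ",
         which(is.na(age) | age <= 0)[1])
  vol <- suppressWarnings(as.numeric(df$volume_mm3))
  if (anyNA(vol) || any(vol < 0))
    stop("unparseable or negative volume at data row ",
         which(is.na(vol) | vol < 0)[1])
  key <- paste(df$case_id, df$structure_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (case, structure) entry at data row ",
         which(duplicated(key))[1], " (",
         df$case_id[which(duplicated(key))[1]], ", ",
         df$structure_id[which(duplicated(key))[1]], ")")
  out <- list()
  for (cid in unique(df$case_id)) {
    i <- df$case_id == cid
    a <- unique(age[i])
    if (length(a) != 1L)
      stop("inconsistent ages for case '", cid, "'")
    out[[cid]] <- VolumeTable(cid, a,
                              stats::setNames(vol[i], df$structure_id[i]))
  }
  unname(out)
}

#' @rdname readVolumeTable
#' @param tables a [VolumeTable-class] or list of them (mm3).
#' @export
writeVolumeTable <- function(tables, path) {
  if (is(tables, "VolumeTable")) tables <- list(tables)
  rows <- lapply(tables, function(v)
    data.frame(case_id = caseId(v), age = caseAge(v),
               structure_id = names(volumes(v)),
               volume_mm3 = unname(volumes(v)), stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = .delimFor(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write z-score tables as TSV
#'
#' Long format: \code{case_id}, \code{age}, \code{structure_id},
#' \code{ratio}, \code{z}, \code{extrapolated}.
#'
#' @param path file path.
#' @return \code{readZScoreTable} returns a list of [ZScoreTable-class].
#' @export
readZScoreTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(unique(df$case_id), function(cid) {
    i <- df$case_id == cid
    new("ZScoreTable", case_id = as.character(cid), age = df$age[i][1],
        ratio = stats::setNames(df$ratio[i], df$structure_id[i]),
        z = stats::setNames(df$z[i], df$structure_id[i]),
        extrapolated = isTRUE(df$extrapolated[i][1]))
  })
}

#' @rdname readZScoreTable
#' @param ztables a [ZScoreTable-class] or list of them.
#' @export
writeZScoreTable <- function(ztables, path) {
  if (is(ztables, "ZScoreTable")) ztables <- list(ztables)
  rows <- lapply(ztables, function(z)
    data.frame(case_id = caseId(z), age = caseAge(z),
               structure_id = names(z@ratio), ratio = unname(z@ratio),
               z = unname(z@z), extrapolated = z@extrapolated,
               stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract structure volumes from a NIfTI label map
#'
#' Per label value, volume = voxel count x voxel volume (mm3) from the
#' header's pixel dimensions.  Labels present in the image but absent from
#' the lookup are ignored with a warning; requires the RNifti package.
#'
#' @param path NIfTI file path (integer-valued label image).
#' @param lookup named character: names are label integer values, values are
#'   structure ids.
#' @param case_id,age case metadata for the returned table.
#' @return a base-level [VolumeTable-class] (mm3).
#' @export
volumesFromLabelmap <- function(path, lookup, case_id = "case", age = 60) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("volumesFromLabelmap requires the RNifti package")
  img <- RNifti::readNifti(path)
  vals <- as.vector(img)
  if (any(abs(vals - round(vals)) > 1e-6))
    stop("label map is not integer-valued")
  vals <- as.integer(round(vals))
  pd <- RNifti::pixdim(img)
  vox <- prod(pd[seq_len(min(3L, length(pd)))])
  tab <- table(vals[vals != 0L])
  present <- names(tab)
  unknown <- setdiff(present, names(lookup))
  if (length(unknown))
    warning("ignoring unlisted label value(s): ",
            paste(unknown, collapse = ", "))
  keep <- intersect(present, names(lookup))
  vols <- stats::setNames(as.numeric(tab[keep]) * vox, lookup[keep])
  VolumeTable(case_id, age, vols)
}

# ---- command-line front end -------------------------------------------------

.cliFlags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument '", a, "'")
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("flag '", a, "' needs a value")
    flags[[substring(a, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

.flagOr <- function(flags, name, default = NULL) {
  v <- flags[[name]]
  if (is.null(v)) {
    if (is.null(default)) stop("missing required flag --", name)
    default
  } else v
}

.cliHierarchy <- function(flags) {
  p <- flags[["hierarchy"]]
  if (is.null(p)) defaultHierarchy() else readHierarchy(p)
}

#' Subcommand command-line entry point
#'
#' Thin shell over the package functions, used by the installed
#' \code{exec/brainvolreport} script.  Subcommands:
#' \describe{
#'   \item{simulate}{\code{--out cohort.csv} with \code{--n}, \code{--seed},
#'     optionally \code{--spec spec.json}; with \code{--atrophy spec.json
#'     --age A --patient-out case.csv} also writes one patient case.}
#'   \item{build-norms}{\code{--controls cohort.csv --out model.json}
#'     (optional \code{--hierarchy h.json}).}
#'   \item{score}{\code{--cases cases.csv --model model.json --out z.tsv}.}
#'   \item{report}{\code{--z z.tsv --out sentences.txt} (optional
#'     \code{--assertions-out a.json}, \code{--dictionary d.json},
#'     \code{--threshold T}).}
#'   \item{evaluate}{\code{--findings coded.tsv --ref RR1 --test AS
#'     --universe a,b,c --out metrics.tsv}.}
#' }
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit status, 0 on success.
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: brainvolreport <subcommand> [--flag value ...]")
    cmd <- args[1]
    flags <- .cliFlags(args[-1])
    h <- .cliHierarchy(flags)
    switch(cmd,
      "simulate" = {
        spec <- if (!is.null(flags[["spec"]])) readCohortSpec(flags[["spec"]])
                else defaultCohortSpec(h)
        if (!is.null(flags[["n"]])) spec@n <- as.integer(flags[["n"]])
        seed <- as.integer(.flagOr(flags, "seed", "1"))
        writeVolumeTable(simulateControls(spec, h, seed = seed),
                         .flagOr(flags, "out"))
        message("simulate: wrote ", spec@n, " controls to ", flags[["out"]])
        if (!is.null(flags[["patient-out"]])) {
          atro <- if (!is.null(flags[["atrophy"]]))
            readAtrophySpec(flags[["atrophy"]]) else AtrophySpec()
          p <- simulatePatient(spec, atro,
                               age = as.numeric(.flagOr(flags, "age", "70")),
                               seed = seed + 1L, h = h)
          writeVolumeTable(p$case, flags[["patient-out"]])
          message("simulate: wrote patient case to ", flags[["patient-out"]])
        }
      },
      "build-norms" = {
        controls <- readVolumeTable(.flagOr(flags, "controls"))
        m <- fitNormative(controls, h)
        writeNormativeModel(m, .flagOr(flags, "out"))
        message("build-norms: fitted ", nrow(modelCoefs(m)),
                " structures on ", length(controls), " controls")
      },
      "score" = {
        cases <- readVolumeTable(.flagOr(flags, "cases"))
        m <- readNormativeModel(.flagOr(flags, "model"))
        zt <- lapply(cases, zscoreCase, m = m, h = h)
        writeZScoreTable(zt, .flagOr(flags, "out"))
        message("score: scored ", length(cases), " case(s)")
      },
      "report" = {
        zt <- readZScoreTable(.flagOr(flags, "z"))
        ckf <- defaultCKF(h, threshold = as.numeric(.flagOr(flags,
                                                            "threshold", "2")))
        dict <- if (!is.null(flags[["dictionary"]]))
          readDictionary(flags[["dictionary"]]) else defaultDictionary()
        out <- .flagOr(flags, "out")
        con <- file(out, "w")
        on.exit(close(con), add = TRUE)
        all_ast <- list()
        for (z in zt) {
          rep <- renderReport(detectPattern(z, ckf), dict, h)
          writeLines(c(paste0("# case ", caseId(z)), sentences(rep)), con)
          a <- assertions(rep)
          if (nrow(a)) a$case_id <- caseId(z)
          all_ast[[length(all_ast) + 1L]] <- a
        }
        if (!is.null(flags[["assertions-out"]])) {
          ast <- do.call(rbind, all_ast)
          jsonlite::write_json(ast, flags[["assertions-out"]],
                               auto_unbox = TRUE, pretty = TRUE)
        }
        message("report: rendered ", length(zt), " case(s) to ", out)
      },
      "evaluate" = {
        fnd <- readCodedFindings(.flagOr(flags, "findings"))
        universe <- strsplit(.flagOr(flags, "universe"), ",",
                             fixed = TRUE)[[1]]
        cases <- unique(fnd$case_id)
        ref <- fnd[fnd$source == .flagOr(flags, "ref"), , drop = FALSE]
        tst <- fnd[fnd$source == .flagOr(flags, "test"), , drop = FALSE]
        cc <- buildContingency(ref, tst, universe, cases)
        tab <- metricsTable(stats::setNames(
          list(cc), paste0(flags[["test"]], "-", flags[["ref"]])))
        utils::write.table(tab, .flagOr(flags, "out"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        message("evaluate: wrote metrics to ", flags[["out"]])
      },
      stop("unknown subcommand '", cmd, "'"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
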