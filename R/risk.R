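#' Disease epidemiology record
#'
#' Holds the optional effect-size statistics used by the cancer-propensity
#' rule: relative risk (RR), hazard ratio (HR), and standardized incidence
#' ratio (SIR). Diseases reported only with an inverse association to
#' cancer carry the protective flag instead of a statistic.
#'
#' @param name Disease name.
#' @param RR,HR,SIR Optional positive effect sizes (\code{NA} if not
#'   reported).
#' @param protective Logical; TRUE for diseases with a reported inverse
#'   association and no elevated statistic.
#' @param group \code{"inflammatory"} (default) or \code{"cancer"}.
#' @return A one-row data.frame of class \code{disease_stats}.
#' @export
disease_stats <- function(name, RR = NA_real_, HR = NA_real_, SIR = NA_real_,
                          protective = FALSE, group = "inflammatory") {
  for (v in list(RR = RR, HR = HR, SIR = SIR)) {
    if (!is.na(v) && v <= 0) stop("Effect sizes must be positive", call. = FALSE)
  }
  structure(data.frame(disease = name, group = group, RR = RR, HR = HR,
                       SIR = SIR, protective = protective,
                       stringsAsFactors = FALSE),
            class = c("disease_stats", "data.frame"))
}

#' Classify a disease as cancer-prone or not
#'
#' The quantitative propensity rule: a chronic inflammatory disease is
#' cancer-prone (CP-CID) when any reported statistic strictly exceeds its
#' threshold — RR > 2, HR > 2, or SIR > 1.4 — and non-cancer-prone
#' (NCP-CID) otherwise. Absent statistics contribute nothing; a protective
#' flag (inverse association with cancer) forces not-prone. Values exactly
#' at a threshold classify as not-prone (strict inequalities).
#'
#' @param s A \code{disease_stats} row (or anything with RR/HR/SIR and
#'   protective fields).
#' @return \code{"prone"} or \code{"not_prone"}.
#' @examples
#' classify_propensity(disease_stats("HBV", HR = 15.77))   # prone
#' classify_propensity(disease_stats("Psoriasis", RR = 1.21)) # not_prone
#' @export
classify_propensity <- function(s) {
  RR <- s$RR; HR <- s$HR; SIR <- s$SIR
  protective <- isTRUE(s$protective)
  if (protective) return("not_prone")
  if (is.na(RR) && is.na(HR) && is.na(SIR)) {
    stop("Insufficient evidence for disease ",
         if (!is.null(s$disease)) s$disease else "",
         ": no statistic reported and no protective flag", call. = FALSE)
  }
  prone <- (!is.na(RR) && RR > 2) || (!is.na(HR) && HR > 2) ||
    (!is.na(SIR) && SIR > 1.4)
  if (prone) "prone" else "not_prone"
}

#' Classify every disease in a registry
#'
#' Applies [classify_propensity()] to each inflammatory disease of a
#' registry and tallies the CP-CID / NCP-CID split. Non-inflammatory rows
#' (group \code{"cancer"}) are passed through with category \code{NA}.
#'
#' @param r A registry data.frame with columns \code{disease},
#'   \code{group}, \code{RR}, \code{HR}, \code{SIR}, \code{protective} —
#'   e.g. from [fenton_disease_registry()] or [read_disease_registry()].
#' @return A \code{disease_classification}: the registry with an added
#'   \code{category} column (\code{"CP-CID"} / \code{"NCP-CID"}) and a
#'   \code{counts} attribute \code{c(cp, ncp)}.
#' @examples
#' classify_registry(fenton_disease_registry())
#' @export
classify_registry <- function(r) {
  stopifnot(is.data.frame(r))
  if (nrow(r) == 0L) {
    out <- cbind(r, category = character(0))
    return(structure(out, counts = c(cp = 0L, ncp = 0L),
                     class = c("disease_classification", "data.frame")))
  }
  if (anyDuplicated(r$disease)) stop("Duplicate disease names", call. = FALSE)
  category <- rep(NA_character_, nrow(r))
  for (i in seq_len(nrow(r))) {
    if (!identical(r$group[i], "inflammatory")) next
    res <- tryCatch(classify_propensity(r[i, ]), error = function(e) {
      stop("Disease ", r$disease[i], ": ", conditionMessage(e), call. = FALSE)
    })
    category[i] <- if (res == "prone") "CP-CID" else "NCP-CID"
  }
  out <- cbind(r, category = category, stringsAsFactors = FALSE)
  counts <- c(cp = sum(category == "CP-CID", na.rm = TRUE),
              ncp = sum(category == "NCP-CID", na.rm = TRUE))
  structure(out, counts = counts,
            class = c("disease_classification", "data.frame"))
}

#' @export
print.disease_classification <- function(x, ...) {
  counts <- attr(x, "counts")
  cat(sprintf("Disease classification: %d CP-CIDs, %d NCP-CIDs\n",
              counts["cp"], counts["ncp"]))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' The nine-disease chronic-inflammation registry
#'
#' The shipped registry of nine chronic inflammatory diseases with their
#' published cancer-risk statistics: asthma (HR 1.36), Alzheimer's disease
#' (inverse association), psoriasis (RR 1.21), irritable bowel syndrome
#' (reduced risk), rheumatoid arthritis (SIR 1.20), ulcerative colitis
#' (SIR 2.4, RR 2.4), Crohn's disease (RR 2.5), non-alcoholic
#' steatohepatitis (HR 7.62), and hepatitis B virus infection (HR 15.77).
#' Under the propensity rule this splits into five NCP-CIDs and four
#' CP-CIDs.
#'
#' @return A registry data.frame suitable for [classify_registry()].
#' @export
fenton_disease_registry <- function() {
  rbind(
    disease_stats("Asthma", HR = 1.36),
    disease_stats("Alzheimer's disease", protective = TRUE),
    disease_stats("Psoriasis", RR = 1.21),
    disease_stats("Irritable bowel syndrome", protective = TRUE),
    disease_stats("Rheumatoid arthritis", SIR = 1.20),
    disease_stats("Ulcerative colitis", SIR = 2.4, RR = 2.4),
    disease_stats("Crohn's disease", RR = 2.5),
    disease_stats("Non-alcoholic steatohepatitis", HR = 7.62),
    disease_stats("Hepatitis B virus", HR = 15.77)
  )
}

#' Read a disease registry TSV
#'
#' Expects columns \code{disease}, \code{group}, \code{RR}, \code{HR},
#' \code{SIR}, \code{protective}; empty cells denote absent statistics.
#'
#' @param path TSV path.
#' @return A registry data.frame.
#' @export
read_disease_registry <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  need <- c("disease", "group", "RR", "HR", "SIR", "protective")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("Registry file missing columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  df$protective <- as.logical(df$protective)
  df$protective[is.na(df$protective)] <- FALSE
  df[need]
}

#' Write a disease classification TSV
#'
#' @param x A \code{disease_classification}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_disease_classification <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
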