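#' @include AllClasses.R
NULL

#' Assemble the integrated feature set F_I for one region
#'
#' Concatenates the deformation and texture descriptors per available
#' protocol (protocols in the fixed order Gd-T1w, T2w, FLAIR; within each
#' protocol the deformation block precedes the texture block) and appends
#' the shape descriptor once. With all three protocols and default
#' parameters the result has `192*3 + 1070*3 + 34 = 3820` features; with
#' Gd-T1w only, `192 + 1070 + 34 = 1296`.
#'
#' @param deformation named list of per-protocol deformation descriptors
#'   (from [assembleFB()]); names must be protocol tags.
#' @param texture named list of per-protocol texture summaries (from
#'   [summarizeTexture()]); must cover the same protocols.
#' @param shape the 34-feature shape descriptor (from [shapeDescriptor()]).
#' @return Named numeric vector; names are `<protocol>.FB.*`,
#'   `<protocol>.FT.*`, then `FS.*`, globally unique.
#' @export
assembleFI <- function(deformation, texture, shape) {
  protos <- names(deformation)
  if (is.null(protos) || !length(protos))
    stop("at least one protocol is required")
  if (!all(protos %in% .PROTOCOLS))
    stop("unknown protocol tag(s): ",
         paste(setdiff(protos, .PROTOCOLS), collapse = ", "))
  if (!setequal(protos, names(texture)))
    stop("deformation and texture protocols differ")
  protos <- .PROTOCOLS[.PROTOCOLS %in% protos]
  out <- numeric(0)
  for (p in protos) {
    fb <- deformation[[p]]
    ft <- texture[[p]]
    names(fb) <- paste(p, "FB", names(fb), sep = ".")
    names(ft) <- paste(p, "FT", names(ft), sep = ".")
    out <- c(out, fb, ft)
  }
  names(shape) <- paste("FS", names(shape), sep = ".")
  out <- c(out, shape)
  if (anyDuplicated(names(out)))
    stop("internal error: duplicated feature names")
  out
}

#' Write a cohort feature table to CSV
#'
#' One row per subject with `subject_id` and `region` as the first columns
#' followed by the features in their stable order. All subjects must carry
#' identical feature names.
#'
#' @param features named list (by subject id) of named numeric vectors.
#' @param region region tag recorded in the table.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeFeatureTable <- function(features, region, path) {
  if (!length(features)) stop("empty cohort")
  ref <- names(features[[1L]])
  bad <- vapply(features, function(f) !identical(names(f), ref), logical(1))
  if (any(bad))
    stop("feature-name mismatch across subjects: ",
         paste(names(features)[bad], collapse = ", "))
  tab <- data.frame(subject_id = names(features), region = region,
                    do.call(rbind, features), check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort feature table written by [writeFeatureTable()]
#'
#' @param path CSV path.
#' @return A data.frame with `subject_id`, `region`, and feature columns.
#' @export
readFeatureTable <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
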