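# Internal helpers: classed conditions and deterministic number formatting.

abort_dsp <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "dsp_error"), call = call))
}

#' @keywords internal
geometric_mean <- function(x) exp(mean(log(x)))

# Fixed scientific notation with 6 significant digits, so that repeated runs
# with the same seed produce byte-identical output files.
format_numeric <- function(x) {
  out <- formatC(x, format = "e", digits = 5)
  out[is.na(x)] <- "NA"
  out
}

format_column <- function(x) {
  if (is.double(x)) format_numeric(x)
  else if (is.logical(x)) ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE"))
  else as.character(x)
}

# Group label "COND-TRT" (e.g. "FLT-SAL") for a set of annotations.
group_label <- function(annotations) {
  paste(annotations$condition, annotations$treatment, sep = "-")
}

check_annotations <- function(annotations) {
  required <- c("aoi_id", "region", "condition", "treatment", "replicate",
                "mouse_id")
  missing <- setdiff(required, names(annotations))
  if (length(missing) > 0) {
    abort_dsp(sprintf("annotation table is missing column(s): %s",
                      paste(missing, collapse = ", ")),
              "dsp_format_error")
  }
  if (anyDuplicated(annotations$aoi_id)) {
    dup <- annotations$aoi_id[duplicated(annotations$aoi_id)][1]
    abort_dsp(sprintf("duplicate AOI id in annotations: '%s'", dup),
              "dsp_format_error")
  }
  key <- paste(annotations$region, annotations$condition,
               annotations$treatment, annotations$replicate)
  if (anyDuplicated(key)) {
    abort_dsp("(region, condition, treatment, replicate) tuples must be unique",
              "dsp_format_error")
  }
  invisible(annotations)
}
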