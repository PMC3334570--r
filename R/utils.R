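# Internal condition helpers.  Every classed error carries
# c("indelLD_<class>", "indelLD_error") so callers/tests can catch precisely.

stop_indelLD <- function(class, message, ...) {
  rlang::abort(message, class = c(paste0("indelLD_", class), "indelLD_error"), ...)
}

warn_indelLD <- function(class, message, ...) {
  rlang::warn(message, class = c(paste0("indelLD_", class), "indelLD_warning"), ...)
}

# Scalar checks used across constructors
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
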