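# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_strucage <- function(..., class) {
  stop(structure(class = c(class, "strucage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Known structure labels and their template node counts
#'
#' Per-hemisphere template vertex counts for the eight supported structures.
#' All counts are powers of two so that four rounds of 2:1 graph coarsening
#' divide them exactly.
#'
#' @return Named integer vector (names are structure labels).
#' @export
#' @examples
#' template_node_counts()[["hippocampus"]]
template_node_counts <- function() {
  c(accumbens = 256L, amygdala = 512L, caudate = 1024L,
    hippocampus = 2048L, pallidum = 512L, putamen = 1024L,
    thalamus = 2048L, cortex = 16384L)
}

structure_labels <- function() names(template_node_counts())

check_structure_label <- function(label) {
  if (!label %in% structure_labels())
    stop_strucage("unknown structure label '", label, "'",
                  class = "strucage_validation_error")
  label
}

# deterministic, seed-free pseudo-random unit vector (for power iteration)
det_unit_vector <- function(n) {
  v <- sin(seq_len(n) * 12.9898) * 43758.5453
  v <- v - floor(v) - 0.5
  if (sqrt(sum(v^2)) < 1e-12) v <- rep(1, n)
  v / sqrt(sum(v^2))
}

is_power_of_two <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
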