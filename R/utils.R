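# Shared constants and helpers.

#' Cytometer channels used throughout the package
#'
#' The eight-parameter panel assumed by the simulator, the gating strategies
#' and the FCS writer: forward/side scatter area and height plus four
#' fluorescence channels (488 nm blue laser B530/B610, yellow-green YG610,
#' red R670).
#'
#' @format Character vector of channel names.
#' @export
SORTGAUGE_CHANNELS <- c("FSC-A", "FSC-H", "SSC-A", "SSC-H",
                        "B530", "YG610", "B610", "R670")

# Pulse-area channels (doubled for a two-particle cluster) and the pulse-height
# channels paired with the area channel they derive from.
AREA_CHANNELS <- c("FSC-A", "SSC-A", "B530", "YG610", "B610", "R670")
HEIGHT_PAIR <- c("FSC-H" = "FSC-A", "SSC-H" = "SSC-A")

# Columns that carry simulation ground truth, never instrument signal.
TRUTH_COLUMNS <- c("population_id", "cluster_size", "outlet")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible stage seed from a run seed
#'
#' All stochastic stages draw their RNG state from one user-visible run seed;
#' each stage mixes in its own tag so stages are independently reproducible
#' and statistically unlinked.
#'
#' @param seed Integer run seed.
#' @param stage Character tag naming the stage.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  bytes <- utf8ToInt(stage)
  h <- sum(bytes * seq_along(bytes)) %% 104729
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 1) %% 2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Normalize channel names to the canonical panel spelling
#'
#' Uppercases and converts underscores to dashes so that e.g. \code{"fsc_a"}
#' maps to \code{"FSC-A"}. Names outside the known panel are returned
#' normalized but otherwise untouched (extra channels are preserved).
#'
#' @param x Character vector of channel names.
#' @return Normalized character vector.
#' @export
normalize_channel_names <- function(x) {
  out <- toupper(gsub("_", "-", trimws(x), fixed = TRUE))
  # tolerate dashless scatter spellings such as "FSCA"
  m <- match(out, gsub("-", "", SORTGAUGE_CHANNELS, fixed = TRUE))
  out[!is.na(m)] <- SORTGAUGE_CHANNELS[m[!is.na(m)]]
  out
}

# Round-trip a double vector through IEEE-754 single precision, the precision
# at which FCS float data is stored.
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          what = "numeric", n = length(x), size = 4L, endian = "little")
}

# Channel columns (everything that is not ground truth) of an event table.
channel_names <- function(events) setdiff(names(events), TRUTH_COLUMNS)

assert_event_table <- function(events, require_channels = NULL) {
  stopifnot(is.data.frame(events))
  ch <- channel_names(events)
  if (!is.null(require_channels)) {
    missing <- setdiff(require_channels, ch)
    if (length(missing) > 0L) {
      stop("event table is missing channel(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  invisible(events)
}
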