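# Run configuration: defaults, YAML load/dump, validation, aliases.

#' Default pipeline configuration
#'
#' Returns the full parameter list with its defaults.  Keys follow the
#' tool's configuration vocabulary; \code{protect_3prime} is accepted as an
#' alias of \code{coordinate} (the 3'-protection width in nt) and
#' \code{subsample_n} as an alias of \code{N}.
#'
#' \describe{
#'   \item{identity}{clustering identity threshold (0.8)}
#'   \item{seq_number_ANI}{members sampled per cluster for the
#'     within-cluster identity estimate (60)}
#'   \item{drop}{drop clusters below \code{min_cluster_size} from panel
#'     assembly (TRUE; with the default minimum size of 1 nothing drops)}
#'   \item{coordinate}{3'-protection distance in nt; mismatches in the
#'     terminal \code{coordinate} bases reject a site; 0 disables (4)}
#'   \item{max_mismatch}{mismatch budget 0-2 (1)}
#'   \item{entropy_max}{window entropy cutoff in bits (3.6)}
#'   \item{primer_len_min, primer_len_max}{scanned window lengths (18-27)}
#'   \item{max_degeneracy}{degeneracy cap during design (64)}
#'   \item{coverage_target}{per-primer design coverage at which expansion
#'     stops (0.98; pair coverage is the intersection of two primers, so
#'     the per-primer target carries headroom over the panel-level goal)}
#'   \item{loss_high, loss_low}{dimer risk thresholds (3.96 / 3.0)}
#'   \item{tm_diff_max}{maximum midpoint Tm difference within a pair, deg
#'     C (8; degenerate expansions already span several degrees and
#'     multiplex amplicon protocols anneal with touchdown ramps)}
#'   \item{min_product, max_product}{product size range in nt (100-1500)}
#'   \item{subsample_n}{sequences aligned per cluster (500)}
#'   \item{seed}{random seed (1)}
#'   \item{aligner}{"builtin" or "mafft"}
#'   \item{host}{optional host FASTA path for specificity screening}
#'   \item{max_windows}{designed windows per cluster and strand (30)}
#' }
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    identity = 0.8,
    seq_number_ANI = 60L,
    drop = TRUE,
    min_cluster_size = 1L,
    coordinate = 4L,
    max_mismatch = 1L,
    entropy_max = 3.6,
    primer_len_min = 18L,
    primer_len_max = 27L,
    max_degeneracy = 64,
    coverage_target = 0.98,
    loss_high = 3.96,
    loss_low = 3.0,
    dimer_strict = FALSE,
    tm_diff_max = 8,
    min_product = 100L,
    max_product = 1500L,
    subsample_n = 500L,
    seed = 1L,
    aligner = "builtin",
    mafft_path = "mafft",
    host = NULL,
    min_run = 4L,
    salt_mM = 50,
    oligo_nM = 50,
    max_offtarget = 0L,
    max_windows = 30L,
    max_pairs_per_cluster = 40L,
    max_alternates = 5L,
    dimer_expansion_cap = 8L
  )
}

.CONFIG_ALIASES <- c(protect_3prime = "coordinate", N = "subsample_n")

.CONFIG_RANGES <- list(
  identity = c(1e-6, 1), max_mismatch = c(0, 2), coordinate = c(0, Inf),
  entropy_max = c(0, Inf), primer_len_min = c(15, Inf),
  primer_len_max = c(15, Inf), max_degeneracy = c(1, Inf),
  coverage_target = c(0, 1), min_product = c(1, Inf),
  max_product = c(1, Inf), subsample_n = c(1, Inf),
  seq_number_ANI = c(1, Inf), min_run = c(1, Inf),
  tm_diff_max = c(0, Inf), max_offtarget = c(0, Inf),
  max_windows = c(1, Inf), min_cluster_size = c(1, Inf)
)

#' Validate (and complete) a configuration
#'
#' Unknown keys are rejected with a message naming the key; aliases are
#' canonicalized; numeric ranges are checked; missing keys take their
#' defaults.
#'
#' @param config Named list of overrides (possibly partial).
#' @return Complete validated parameter list.
#' @export
validate_config <- function(config = list()) {
  def <- default_config()
  if (length(config)) {
    nm <- names(config)
    nm[nm %in% names(.CONFIG_ALIASES)] <-
      .CONFIG_ALIASES[nm[nm %in% names(.CONFIG_ALIASES)]]
    names(config) <- nm
    unknown <- setdiff(nm, names(def))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           "; known keys: ", paste(names(def), collapse = ", "),
           call. = FALSE)
    def[nm] <- config
  }
  for (key in names(.CONFIG_RANGES)) {
    v <- def[[key]]
    r <- .CONFIG_RANGES[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < r[1] || v > r[2])
      stop(sprintf("config key '%s' out of range [%s, %s]: %s",
                   key, r[1], r[2], paste(v, collapse = ",")),
           call. = FALSE)
  }
  if (def$primer_len_min > def$primer_len_max)
    stop("primer_len_min exceeds primer_len_max", call. = FALSE)
  if (def$min_product > def$max_product)
    stop("min_product exceeds max_product", call. = FALSE)
  if (!def$aligner %in% c("builtin", "mafft"))
    stop("config key 'aligner' must be 'builtin' or 'mafft'", call. = FALSE)
  def
}

#' Load a YAML configuration file
#'
#' @param path Path to a YAML file of parameter overrides.
#' @return Complete validated parameter list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  validate_config(cfg)
}

#' Write a configuration to YAML
#'
#' A dumped configuration reloads to an identical parameter list.
#'
#' @param config Parameter list.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}
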