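## Bundled case-study fixtures and a random-network generator.

FIXTURE_FILES <- list(
  yeast11 = list(network = "yeast11_network.txt", mode = "weighted"),
  mcf7_p53 = list(network = "mcf7_p53_synthetic_network.csv",
                  fates = "mcf7_fates.txt", mode = "weighted",
                  perturbations = c(E = "mcf7_pert_E.txt",
                                    N = "mcf7_pert_N.txt",
                                    W = "mcf7_pert_W.txt",
                                    EN = "mcf7_pert_EN.txt",
                                    EW = "mcf7_pert_EW.txt",
                                    NW = "mcf7_pert_NW.txt",
                                    ENW = "mcf7_pert_ENW.txt")),
  crc201 = list(network = "crc201_synthetic_network.csv",
                rules = "crc201_synthetic_rules.txt",
                fates = "crc201_fates.txt", mode = "rules",
                perturbations = c(A = "crc201_pert_A.txt",
                                  AK = "crc201_pert_AK.txt",
                                  AKP = "crc201_pert_AKP.txt",
                                  AKPT = "crc201_pert_AKPT.txt",
                                  HCT116 = "crc201_pert_HCT116.txt"))
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "attractorscape")
  if (!nzchar(p)) stop("fixture file not found: ", file)
  p
}

#' Load a bundled case-study fixture
#'
#' Three fixtures ship with the package:
#'
#' * `yeast11` -- the 11-node budding-yeast cell-cycle network (weighted
#'   mode), transcribed from Li et al. (2004) PNAS 101:4781. Seven point
#'   attractors under exhaustive deterministic analysis; the largest basin
#'   (1764/2048) is the stationary-G1 state.
#' * `mcf7_p53` -- a *synthetic* 16-node p53-signalling network (weighted
#'   mode, basal values) with named perturbation files for Etoposide (E),
#'   Nutlin (N), WIP1 knock-down (W) and their combinations, plus fate
#'   logic. See the file header and the methods vignette for its design.
#' * `crc201` -- a *synthetic* 201-node signalling network (rules mode,
#'   13 input and 8 output nodes) with fate logic and driver-mutation
#'   perturbation files (cumulative APC/KRAS/PTEN/TP53 arms, plus an
#'   HCT-116-like RAS/PI3K arm).
#'
#' @param name `"yeast11"`, `"mcf7_p53"` or `"crc201"`.
#' @param warn_missing_rules passed to [attach_rules()] for rules fixtures.
#' @return list with elements `spec` (a [network_spec()], rules attached
#'   where applicable), `mode`, `fates` (a [fate_rules()] or `NULL`),
#'   `perturbations` (named list of perturbation sets), `input_nodes` and
#'   `output_nodes` (for `crc201`), and `files` (paths used).
#' @export
load_fixture <- function(name, warn_missing_rules = FALSE) {
  if (!name %in% names(FIXTURE_FILES)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(FIXTURE_FILES), collapse = ", "))
  }
  info <- FIXTURE_FILES[[name]]
  files <- list(network = fixture_path(info$network))
  spec <- read_network(files$network)
  if (!is.null(info$rules)) {
    files$rules <- fixture_path(info$rules)
    spec <- attach_rules(spec, read_rules(files$rules),
                         warn_missing = warn_missing_rules)
  }
  fates <- NULL
  if (!is.null(info$fates)) {
    files$fates <- fixture_path(info$fates)
    fates <- read_fate_rules(files$fates, fallback = "quiescent")
  }
  perts <- list()
  if (!is.null(info$perturbations)) {
    files$perturbations <- vapply(info$perturbations, fixture_path, "")
    perts <- lapply(files$perturbations, read_perturbations)
  }
  out <- list(name = name, spec = spec, mode = info$mode, fates = fates,
              perturbations = perts, files = files)
  if (name == "crc201") {
    out$input_nodes <- c("EGF", "IGF", "HGF", "WNT", "TGFB", "DNA_DAM",
                         "HYPOXIA", "NUTRIENT", "FASL", "IL6", "NOTCHL",
                         "OXSTRESS", "BMP")
    out$output_nodes <- c("PROLIF", "APOP", "ARREST", "EMT", "MIG", "ANGIO",
                          "DIFF", "SEN")
  }
  out
}

#' MD5 checksums of the bundled fixture files
#'
#' Used by the test suite to pin fixture content: a silent edit of any
#' bundled file changes its checksum and fails the integrity test.
#'
#' @return named character vector of MD5 sums, one per bundled file.
#' @export
fixture_checksums <- function() {
  dir <- system.file("extdata", package = "attractorscape")
  files <- sort(list.files(dir, full.names = TRUE))
  sums <- tools::md5sum(files)
  names(sums) <- basename(names(sums))
  sums
}

#' Generate a reproducible random Boolean network
#'
#' Draws each of the `N^2` directed edges (self-loops included)
#' independently with probability `edge_density` and assigns each realized
#' edge a weight sampled uniformly from `weight_set`. Basal values are zero
#' and all nodes start off. Useful for property-style testing and
#' ensemble studies.
#'
#' @param n_nodes number of nodes.
#' @param edge_density edge probability in `(0, 1]`.
#' @param weight_set non-empty vector of candidate weights.
#' @param seed integer seed; identical seeds give identical networks.
#' @return a [network_spec()] with nodes `n1 ... nN`.
#' @export
random_network <- function(n_nodes, edge_density = 0.3,
                           weight_set = c(-1, 1), seed = NULL) {
  stopifnot(n_nodes >= 1)
  if (!length(weight_set)) stop("weight_set must be non-empty")
  if (edge_density <= 0 || edge_density > 1) {
    stop("edge_density must be in (0, 1]")
  }
  W <- with_local_seed(seed, {
    present <- matrix(stats::runif(n_nodes^2) < edge_density, n_nodes)
    w <- matrix(sample(weight_set, n_nodes^2, replace = TRUE), n_nodes)
    w * present
  })
  network_spec(paste0("n", seq_len(n_nodes)), W = W)
}
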