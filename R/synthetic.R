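## Planted-module benchmark generator: tensors with known gene-set x
## condition-set x consecutive-time-interval modules on a zero background,
## corrupted by sparse noise at a given density.

#' Generate a tensor with planted modules
#'
#' Builds an \code{n1 x n2 x n3} tensor whose background is zero and which
#' contains \code{K} planted modules, each a gene set x condition set x
#' consecutive time interval filled with i.i.d. Uniform(signalLow,
#' signalHigh) values. Afterwards a fraction \code{noiseDensity} of all
#' tensor cells, chosen uniformly at random, is corrupted: by default the
#' chosen cells are overwritten with Uniform(signalLow, signalHigh) noise;
#' with \code{noiseType = "additive"} Gaussian noise of standard deviation
#' \code{noiseSd} is added to them instead.
#'
#' Under the default disjoint placement, gene sets of distinct modules are
#' pairwise disjoint (likewise condition sets), drawn as random subsets of
#' the axes. Time intervals are placed pairwise non-overlapping (uniformly at
#' random among such arrangements) whenever \code{K * intervalLength <= n3};
#' when the intervals cannot all fit disjointly they are placed independently
#' per module and may overlap, which caps the attainable evaluation scores --
#' deliberately so, as crowding the time axis is what makes many-module
#' benchmarks hard. The defaults reproduce the benchmark geometry of
#' the factorization's evaluation protocol: 400 genes x 400 conditions x 50
#' time-points with 40-gene x 40-condition x 10-time-point modules.
#'
#' @param n1,n2,n3 tensor dimensions
#' @param K number of planted modules
#' @param genesPerModule,conditionsPerModule module sizes on the first two
#'   axes
#' @param intervalLength length of each module's consecutive time interval
#' @param noiseDensity fraction in [0, 1] of tensor cells to corrupt
#' @param signalLow,signalHigh bounds of the uniform signal distribution
#' @param disjoint require pairwise-disjoint gene and condition sets
#'   (default); with \code{FALSE}, sets are sampled independently and may
#'   overlap
#' @param noiseType \code{"overwrite"} (default) or \code{"additive"}
#' @param noiseSd standard deviation for additive noise
#' @param seed RNG seed; identical arguments give identical output
#' @return list with elements \code{tensor} (an
#'   \linkS4class{InteractionTensor}) and \code{truth} (a
#'   \linkS4class{GroundTruth})
#' @examples
#' sim <- generatePlantedTensor(n1 = 40, n2 = 40, n3 = 12, K = 2,
#'                              genesPerModule = 8, conditionsPerModule = 8,
#'                              intervalLength = 4, noiseDensity = 0.01,
#'                              seed = 3)
#' sim$truth
#' @export
generatePlantedTensor <- function(n1 = 400, n2 = 400, n3 = 50, K = 3,
                                  genesPerModule = 40,
                                  conditionsPerModule = 40,
                                  intervalLength = 10, noiseDensity = 0.005,
                                  signalLow = 0.6, signalHigh = 1.0,
                                  disjoint = TRUE,
                                  noiseType = c("overwrite", "additive"),
                                  noiseSd = 0.1, seed = 1L) {
    noiseType <- match.arg(noiseType)
    if (noiseDensity < 0 || noiseDensity > 1)
        stop("'noiseDensity' must lie in [0, 1]")
    if (intervalLength > n3)
        stop("'intervalLength' exceeds the time-axis length")
    if (disjoint && (K * genesPerModule > n1 || K * conditionsPerModule > n2))
        stop("disjoint placement infeasible: K * module size exceeds the axis ",
             "length (set disjoint = FALSE to allow overlap)")
    seed <- as.integer(seed)
    set.seed(seed)

    a <- array(0, c(n1, n2, n3))
    gpool <- sample.int(n1)
    cpool <- sample.int(n2)
    ## time intervals: pairwise disjoint when they all fit on the axis
    ## (uniform over non-overlapping arrangements via a stars-and-bars draw),
    ## otherwise independent random starts that may overlap
    if (K * intervalLength <= n3) {
        x <- sort(sample.int(n3 - K * intervalLength + K, K))
        starts <- x + (seq_len(K) - 1L) * (intervalLength - 1L)
    } else {
        starts <- sample.int(n3 - intervalLength + 1L, K, replace = TRUE)
    }
    modules <- vector("list", K)
    for (k in seq_len(K)) {
        g <- if (disjoint)
            gpool[((k - 1L) * genesPerModule + 1L):(k * genesPerModule)]
        else sample.int(n1, genesPerModule)
        cc <- if (disjoint)
            cpool[((k - 1L) * conditionsPerModule + 1L):(k * conditionsPerModule)]
        else sample.int(n2, conditionsPerModule)
        start <- starts[k]
        tt <- start:(start + intervalLength - 1L)
        a[g, cc, tt] <- stats::runif(length(g) * length(cc) * length(tt),
                                     signalLow, signalHigh)
        modules[[k]] <- new("PlantedModule",
                            genes = sort(as.integer(g)),
                            conditions = sort(as.integer(cc)),
                            timeStart = as.integer(start),
                            timeEnd = as.integer(start + intervalLength - 1L),
                            signalLow = signalLow, signalHigh = signalHigh)
    }
    nNoise <- round(noiseDensity * length(a))
    if (nNoise > 0) {
        cells <- sample.int(length(a), nNoise)
        if (noiseType == "overwrite") {
            a[cells] <- stats::runif(nNoise, signalLow, signalHigh)
        } else {
            a[cells] <- a[cells] + stats::rnorm(nNoise, 0, noiseSd)
        }
    }
    wid <- function(n) max(2L, nchar(n))
    labs <- list(sprintf("g%0*d", wid(n1), seq_len(n1)),
                 sprintf("c%0*d", wid(n2), seq_len(n2)),
                 sprintf("t%0*d", wid(n3), seq_len(n3)))
    tensor <- InteractionTensor(a, labs[[1]], labs[[2]], labs[[3]])
    truth <- new("GroundTruth", modules = modules,
                 noiseDensity = noiseDensity, seed = seed,
                 dims = as.integer(c(n1, n2, n3)), axisLabels = labs)
    list(tensor = tensor, truth = truth)
}
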