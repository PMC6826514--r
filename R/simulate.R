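#' Configuration of the synthetic spot-level dataset generator
#'
#' Emulates a replicated two-colour-microarray-like design: a set of
#' conditions measured in four biological replicates each, every gene probed
#' redundantly by 1..28 spots (most by one), multiplicative (log2-additive
#' Gaussian) replicate noise with a programmable coefficient of variation,
#' latent replicate-level factors inducing signed coordination between
#' designated genes, spot-level noise independent across spots, and
#' foreground/background channel intensities so validity filtering can be
#' exercised.
#'
#' A latent-factor module is a list with elements \code{genes} (symbols),
#' \code{loadings} (same length, in [-1, 1]), \code{strength} (fraction of
#' the replicate-level variance the factor carries, in [0, 1]) and optional
#' \code{conditions} (labels where the module is active; default all).  Two
#' member genes g, h then have true replicate correlation
#' \code{strength * loading_g * loading_h} in the active conditions.
#'
#' @param n_genes number of genes.
#' @param conditions condition labels; defaults to the five-paradigm layout
#'   (unstimulated plus two stimulation patterns at two durations).
#' @param replicates biological replicates per condition (default 4).
#' @param redundancy_sampler function(n) returning n spot redundancies in
#'   1..28; the default concentrates on 1 with a geometric tail.
#' @param base_level_log2 per-gene baseline on the log2 scale: a numeric
#'   vector of length \code{n_genes} or a function(n) drawing one.
#' @param replicate_cv target replicate-level CV in percent (scalar or
#'   per-gene vector).
#' @param modules list of latent-factor modules (see above).
#' @param spot_noise_cv spot-level noise CV in percent.
#' @param background_mean,background_cv background intensity distribution.
#' @param scale foreground intensity per expression unit.
#' @param fraction_control,fraction_corrupted,fraction_low_signal fractions
#'   of spots flagged/injected for filter testing.
#' @param empirical standardize the replicate draws so that realized
#'   second moments match the programmed ones exactly (analogous to
#'   \code{MASS::mvrnorm(empirical = TRUE)}); default TRUE.  With few
#'   replicates this removes second-moment sampling error from the ground
#'   truth, making recovery tests sharp.
#' @return a \code{simulation_config} list.
#' @export
simulationConfig <- function(n_genes = 200L,
                             conditions = c("UNST", "18/1_2h", "18/1_5h",
                                            "90/5_2h", "90/5_5h"),
                             replicates = 4L,
                             redundancy_sampler = NULL,
                             base_level_log2 = NULL,
                             replicate_cv = 20,
                             modules = list(),
                             spot_noise_cv = 5,
                             background_mean = 100, background_cv = 20,
                             scale = 1000,
                             fraction_control = 0.02,
                             fraction_corrupted = 0.01,
                             fraction_low_signal = 0.02,
                             empirical = TRUE) {
    stopifnot(n_genes >= 1, replicates >= 2, length(conditions) >= 1,
              all(replicate_cv >= 0), spot_noise_cv >= 0,
              background_mean >= 0, background_cv >= 0, scale > 0)
    fr <- c(fraction_control, fraction_corrupted, fraction_low_signal)
    if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
    if (is.null(redundancy_sampler))
        redundancy_sampler <- function(n) {
            p <- c(0.6, 0.4 * stats::dgeom(0:26, 0.35) /
                        sum(stats::dgeom(0:26, 0.35)))
            sample.int(28L, n, replace = TRUE, prob = p)
        }
    if (is.null(base_level_log2))
        base_level_log2 <- function(n) stats::rnorm(n, 0, 1.5)
    for (m in modules) {
        stopifnot(length(m$genes) == length(m$loadings),
                  all(abs(m$loadings) <= 1),
                  m$strength >= 0, m$strength <= 1)
    }
    structure(list(n_genes = as.integer(n_genes), conditions = conditions,
                   replicates = as.integer(replicates),
                   redundancy_sampler = redundancy_sampler,
                   base_level_log2 = base_level_log2,
                   replicate_cv = replicate_cv, modules = modules,
                   spot_noise_cv = spot_noise_cv,
                   background_mean = background_mean,
                   background_cv = background_cv, scale = scale,
                   fraction_control = fraction_control,
                   fraction_corrupted = fraction_corrupted,
                   fraction_low_signal = fraction_low_signal,
                   empirical = isTRUE(empirical)),
              class = "simulation_config")
}

# percent CV -> log2-scale SD under the lognormal model
.cvToLog2Sd <- function(cv_percent) {
    sqrt(log(1 + (cv_percent / 100)^2)) / log(2)
}

.standardize <- function(v) {
    v <- v - mean(v)
    s <- stats::sd(v)
    if (s == 0) v else v / s
}

#' Generate a seeded synthetic dataset with ground truth
#'
#' Replicate-level log2 expression of gene g in replicate r is
#' \code{base_g + sigma_g * (sum_m sqrt(strength_m) * loading_gm * f_mr +
#' sqrt(1 - sum_m strength_m * loading_gm^2) * e_gr)} with standard-normal
#' factor draws \code{f} shared across genes and idiosyncratic draws
#' \code{e}; spot values add independent log2 spot noise; foreground
#' intensity is \code{scale * 2^value} plus the recorded background draw.
#' Control, corrupted and low-signal spots are injected at the configured
#' fractions and recorded in the truth tables.
#'
#' In \code{empirical} mode the factor draws are standardized and the
#' idiosyncratic draws orthogonalized against them, so realized per-gene
#' replicate variance and pairwise correlation signs match the programmed
#' values exactly rather than up to n = 4 sampling error.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed; the same config + seed reproduce the dataset
#'   bit-identically.
#' @return a \linkS4class{SimulatedDataset}.
#' @export
simulateDataset <- function(config, seed = 1L) {
    stopifnot(inherits(config, "simulation_config"))
    set.seed(as.integer(seed))
    ng <- config$n_genes
    nrep <- config$replicates
    genes <- sprintf("G%04d", seq_len(ng))
    cvs <- rep_len(config$replicate_cv, ng)
    sig <- .cvToLog2Sd(cvs)
    base <- if (is.function(config$base_level_log2))
        config$base_level_log2(ng) else rep_len(config$base_level_log2, ng)
    # per-gene factor structure
    load_mat <- matrix(0, ng, length(config$modules))
    active <- vector("list", length(config$modules))
    for (mi in seq_along(config$modules)) {
        m <- config$modules[[mi]]
        gi <- match(m$genes, genes)
        if (anyNA(gi)) stop("module references unknown gene(s)")
        load_mat[gi, mi] <- sqrt(m$strength) * m$loadings
        active[[mi]] <- m$conditions %||% config$conditions
    }
    resid_var <- 1 - rowSums(load_mat^2)
    if (any(resid_var < -1e-9))
        stop("infeasible CV decomposition: factor variance exceeds the ",
             "programmed replicate variance for some gene(s)")
    resid_var <- pmax(resid_var, 0)

    redundancy <- config$redundancy_sampler(ng)
    stopifnot(all(redundancy >= 1))
    spot_gene <- rep(seq_len(ng), times = redundancy)
    n_gene_spots <- length(spot_gene)
    n_control <- round(config$fraction_control * n_gene_spots /
                       max(1 - config$fraction_control, 1e-9))
    spot_id <- sprintf("S%05d", seq_len(n_gene_spots + n_control))
    transcript <- c(genes[spot_gene],
                    sprintf("CTRL%03d", seq_len(n_control)))
    is_control <- c(rep(FALSE, n_gene_spots), rep(TRUE, n_control))
    n_spots <- length(spot_id)
    is_corrupted <- rep(FALSE, n_spots)
    n_corr <- round(config$fraction_corrupted * n_gene_spots)
    if (n_corr > 0)
        is_corrupted[sample(which(!is_control), n_corr)] <- TRUE

    sigma_spot <- .cvToLog2Sd(config$spot_noise_cv)
    n_cond <- length(config$conditions)
    n_samp <- n_cond * nrep
    samp_cond <- rep(config$conditions, each = nrep)
    samp_rep <- rep(seq_len(nrep), times = n_cond)

    log2val <- matrix(NA_real_, n_spots, n_samp)
    truth_genes <- vector("list", n_cond)
    for (ci in seq_len(n_cond)) {
        cond <- config$conditions[ci]
        fmat <- matrix(stats::rnorm(length(config$modules) * nrep),
                       nrow = nrep)
        if (config$empirical && ncol(fmat)) {
            if (ncol(fmat) + 2 > nrep)
                stop("empirical mode supports at most replicates - 2 ",
                     "factors")
            fmat <- apply(fmat, 2, .standardize)
            if (ncol(fmat) > 1) {    # mutually orthogonal factor draws
                q <- qr.Q(qr(fmat))
                fmat <- apply(q, 2, .standardize)
            }
        }
        on_mask <- vapply(active, function(a) cond %in% a, TRUE)
        lm_c <- load_mat
        lm_c[, !on_mask] <- 0
        rv_c <- pmax(1 - rowSums(lm_c^2), 0)
        dev <- matrix(0, ng, nrep)
        for (g in seq_len(ng)) {
            e <- stats::rnorm(nrep)
            used <- which(lm_c[g, ] != 0)
            if (config$empirical) {
                e <- e - mean(e)
                if (length(used)) {
                    fu <- fmat[, used, drop = FALSE]
                    e <- e - fu %*% solve(crossprod(fu), crossprod(fu, e))
                }
                e <- .standardize(as.vector(e))
            }
            dev[g, ] <- sig[g] *
                (as.vector(fmat %*% lm_c[g, ]) + sqrt(rv_c[g]) * e)
        }
        y <- base + dev      # genes x replicates, log2 scale
        cols <- which(samp_cond == cond)
        for (r in seq_len(nrep)) {
            noise <- if (sigma_spot > 0)
                stats::rnorm(n_spots, 0, sigma_spot) else 0
            v <- numeric(n_spots)
            v[seq_len(n_gene_spots)] <- y[spot_gene, r]
            v[is_control] <- 0
            log2val[, cols[r]] <- v + noise
        }
        truth_genes[[ci]] <- data.frame(
            transcript_id = genes, condition = cond,
            true_level = config$scale * 2^base,
            true_cv = cvs, stringsAsFactors = FALSE)
    }
    bg <- matrix(pmax(stats::rnorm(n_spots * n_samp, config$background_mean,
                                   config$background_mean *
                                   config$background_cv / 100), 0),
                 n_spots, n_samp)
    fg <- config$scale * 2^log2val + bg

    # inject low-signal failures: one random sample drops below the SNR bar
    n_low <- round(config$fraction_low_signal * n_gene_spots)
    eligible <- which(!is_control & !is_corrupted)
    low_idx <- if (n_low > 0) sample(eligible, min(n_low, length(eligible)))
               else integer(0)
    for (i in low_idx) {
        j <- sample.int(n_samp, 1)
        fg[i, j] <- 1.5 * bg[i, j]   # below the default factor of 2
    }
    label <- rep("valid", n_spots)
    label[low_idx] <- "low_signal"
    label[is_corrupted] <- "corrupted"
    label[is_control] <- "control"

    dimnames(fg) <- dimnames(bg) <-
        list(spot_id, paste(samp_cond, samp_rep, sep = "."))
    rd <- DataFrame(spot_id = spot_id, transcript_id = transcript,
                    is_control = is_control, is_corrupted = is_corrupted)
    cd <- DataFrame(condition = samp_cond, replicate = samp_rep,
                    row.names = colnames(fg))
    se <- SummarizedExperiment(
        assays = list(foreground = fg, background = bg,
                      signal = pmax(fg - bg, 1e-3)),
        rowData = rd, colData = cd)
    se <- methods::new("SpotExperiment", se)

    pairs <- .truthPairs(config, genes, load_mat, active)
    truth <- list(genes = do.call(rbind, truth_genes),
                  pairs = pairs,
                  spots = data.frame(spot_id = spot_id,
                                     transcript_id = transcript,
                                     label = label,
                                     stringsAsFactors = FALSE))
    methods::new("SimulatedDataset", raw = se, truth = truth,
                 config = unclass(config), seed = as.integer(seed))
}

.truthPairs <- function(config, genes, load_mat, active) {
    out <- list()
    for (cond in config$conditions) {
        on <- vapply(active, function(a) cond %in% a, TRUE)
        lm_c <- load_mat
        if (length(on)) lm_c[, !on] <- 0
        members <- which(rowSums(lm_c != 0) > 0)
        if (length(members) < 2) next
        idx <- utils::combn(members, 2)
        rho <- vapply(seq_len(ncol(idx)), function(k) {
            sum(lm_c[idx[1, k], ] * lm_c[idx[2, k], ])
        }, 0)
        keep <- rho != 0
        if (!any(keep)) next
        out[[length(out) + 1L]] <- data.frame(
            gene_a = genes[idx[1, keep]], gene_b = genes[idx[2, keep]],
            condition = cond, true_rho = rho[keep],
            true_sign = ifelse(rho[keep] > 0, "+", "-"),
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(gene_a = character(), gene_b = character(),
                          condition = character(), true_rho = numeric(),
                          true_sign = character(), stringsAsFactors = FALSE))
    do.call(rbind, out)
}

#' Write ground-truth tables of a simulated dataset
#'
#' Emits machine-readable truth aligned with the pipeline output schemas:
#' \code{truth_genes.tsv} (per-gene true level and CV per condition),
#' \code{truth_pairs.tsv} (designated pairs with true correlation and
#' sign) and \code{truth_spots.tsv} (per-spot filter labels).
#'
#' @param dataset a \linkS4class{SimulatedDataset}.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
groundTruthReport <- function(dataset, dir) {
    stopifnot(is(dataset, "SimulatedDataset"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    truth <- dataset@truth
    paths <- c(genes = file.path(dir, "truth_genes.tsv"),
               pairs = file.path(dir, "truth_pairs.tsv"),
               spots = file.path(dir, "truth_spots.tsv"))
    for (nm in names(paths))
        utils::write.table(truth[[nm]], paths[nm], sep = "\t",
                           quote = FALSE, row.names = FALSE)
    invisible(paths)
}

#' Write a simulated dataset as a long-format spot table
#'
#' The emitted TSV reads back with \code{\link{readSpotTable}} under the
#' default two-channel dialect.
#'
#' @param dataset a \linkS4class{SimulatedDataset}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeSpotTable <- function(dataset, path) {
    se <- rawData(dataset)
    rd <- rowData(se); cd <- colData(se)
    fg <- assay(se, "foreground"); bg <- assay(se, "background")
    long <- data.frame(
        spot_id = rep(rd$spot_id, times = ncol(se)),
        transcript_id = rep(rd$transcript_id, times = ncol(se)),
        condition = rep(cd$condition, each = nrow(se)),
        replicate = rep(cd$replicate, each = nrow(se)),
        foreground = as.vector(fg),
        background = as.vector(bg),
        is_control = rep(rd$is_control, times = ncol(se)),
        is_corrupted = rep(rd$is_corrupted, times = ncol(se)))
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
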