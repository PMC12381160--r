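# Figures of merit, success labelling, racemate-grouped cross-validation,
# the two-stage training procedure with balanced sampling, and the
# ranking/evaluation metrics.

#' Figures of merit of one resolution experiment
#'
#' `m_frac = m_solid / m_initial`, `ee = |chi_R - chi_S|`, and the combined
#' score `z = m_frac * ee`. For a racemic feed, `z = 0.5` is the ideal
#' resolution (half of the substrate crystallises, enantiopure).
#'
#' @param m_solid,m_initial substrate masses (same units, `m_initial > 0`)
#' @param chi_R,chi_S solid-phase molar fractions of the two enantiomers
#' @return list with `m_frac`, `ee`, `z`, `chi_R`, `chi_S`, `m_solid`,
#'   `m_initial`
#' @export
figuresOfMerit <- function(m_solid, m_initial, chi_R, chi_S) {
  stopifnot(m_solid >= 0, m_initial > 0, chi_R >= 0, chi_R <= 1,
            chi_S >= 0, chi_S <= 1)
  if (m_solid > m_initial)
    stop("m_solid cannot exceed m_initial", call. = FALSE)
  m_frac <- m_solid / m_initial
  ee <- abs(chi_R - chi_S)
  list(m_frac = m_frac, ee = ee, z = m_frac * ee,
       chi_R = chi_R, chi_S = chi_S, m_solid = m_solid, m_initial = m_initial)
}

#' Success labels for experiment records
#'
#' Adds three logical columns: `retrospective_hit` (`m_frac > 0.20` and
#' `ee > 0.25`, strict), `low_noise` (`m_frac >= 0.20`, the subset whose
#' labels are trusted for classification fine-tuning), and
#' `prospective_hit` (`full_dissolution` and `z = m_frac * ee >= 0.25`).
#'
#' @param df experiment data.frame with `m_frac`, `ee` and optionally
#'   `full_dissolution`
#' @return the data.frame with label columns appended
#' @export
labelRecords <- function(df) {
  df$retrospective_hit <- df$m_frac > 0.20 & df$ee > 0.25
  df$low_noise <- df$m_frac >= 0.20
  fd <- if ("full_dissolution" %in% names(df)) df$full_dissolution else NA
  df$z <- df$m_frac * df$ee
  df$prospective_hit <- !is.na(fd) & fd & df$z >= 0.25
  df
}

#' Racemate-grouped k-fold split plan
#'
#' Racemates are shuffled by seed and greedily assigned (largest first among
#' the shuffled order's count ties are left as shuffled) to the fold with the
#' fewest records, so no racemate ever spans folds and fold sizes stay
#' balanced.
#'
#' @param racemateIds character vector, one entry per record
#' @param k number of folds
#' @param seed shuffle seed
#' @return list with `k`, `racemateFold` (named integer) and `fold`
#'   (per-record integer)
#' @export
groupKFold <- function(racemateIds, k = 5L, seed = 1L) {
  racemateIds <- as.character(racemateIds)
  rac <- unique(racemateIds)
  if (length(rac) < k)
    stop("need at least k = ", k, " distinct racemates, got ", length(rac),
         call. = FALSE)
  counts <- table(racemateIds)
  ord <- withSeed(seed, sample(rac))
  foldSize <- numeric(k)
  assign <- integer(length(ord))
  names(assign) <- ord
  for (r in ord) {
    f <- which.min(foldSize)
    assign[r] <- f
    foldSize[f] <- foldSize[f] + counts[[r]]
  }
  list(k = as.integer(k), racemateFold = assign,
       fold = unname(assign[racemateIds]))
}

#' Balanced batch sampling indices
#'
#' Samples record indices with replacement, weighting the two classes so a
#' batch contains successful and unsuccessful resolutions in equal expected
#' proportion.
#'
#' @param labels logical class labels
#' @param batchSize batch size
#' @return integer indices of length `batchSize`
#' @export
sampleBalancedIndices <- function(labels, batchSize) {
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("balanced sampling requires both classes present", call. = FALSE)
  w <- ifelse(labels, 0.5 / nPos, 0.5 / nNeg)
  sample.int(length(labels), batchSize, replace = TRUE, prob = w)
}

stage1Targets <- function(records, target = c("m_frac_ee", "z")) {
  target <- match.arg(target)
  if (target == "m_frac_ee") cbind(m_frac = records$m_frac, ee = records$ee)
  else cbind(z = records$m_frac * records$ee)
}

checkPairsComplete <- function(pairs, ids = NULL) {
  bad <- which(vapply(pairs, is.null, logical(1)))
  if (length(bad)) {
    nm <- if (is.null(ids)) bad else ids[bad]
    stop("missing pair tensors for record(s): ",
         paste(utils::head(nm, 5), collapse = ", "), call. = FALSE)
  }
}

#' Stage-1 regression pre-training
#'
#' Trains the full model by Adam on the squared error of the regression
#' targets, using every record (including the high-uncertainty low-mass
#' subset). If `racemates` is given, 10\% of the training racemates are
#' carved out as a validation split and the parameters with the best
#' validation loss are returned (early stopping); the split never crosses a
#' racemate.
#'
#' @param model an initialised [DualStreamModel-class] with a regression head
#' @param pairs list of [PairTensors-class], one per record
#' @param targets numeric target matrix (rows = records)
#' @param steps,batchSize,lr optimisation controls
#' @param seed batch-order / dropout seed
#' @param racemates optional racemate id per record (enables validation split)
#' @param valFraction fraction of racemates held out for early stopping
#' @param evalEvery validation cadence in steps
#' @return list with `model`, `loss` (training trace), `valLoss`
#' @export
stage1Train <- function(model, pairs, targets, steps = 300L, batchSize = 16L,
                        lr = 1e-3, seed = 1L, racemates = NULL,
                        valFraction = 0.1, evalEvery = 25L) {
  n <- length(pairs)
  if (n == 0L) stop("empty training set", call. = FALSE)
  checkPairsComplete(pairs)
  targets <- as.matrix(targets)
  stopifnot(nrow(targets) == n)
  trainIdx <- seq_len(n); valIdx <- integer(0)
  if (!is.null(racemates) && valFraction > 0) {
    rac <- unique(as.character(racemates))
    nVal <- max(1L, floor(length(rac) * valFraction))
    if (length(rac) - nVal >= 1L) {
      valRac <- withSeed(seed + 7L, sample(rac, nVal))
      valIdx <- which(racemates %in% valRac)
      trainIdx <- setdiff(seq_len(n), valIdx)
    }
  }
  evalLoss <- function(m, idx) {
    mean(vapply(idx, function(i) {
      out <- modelForward(m, pairs[[i]])$output
      mean((out - targets[i, ])^2)
    }, numeric(1)))
  }
  withSeed(seed, {
    opt <- adamInit(model@params)
    lossTrace <- numeric(0)
    best <- list(params = model@params, val = Inf)
    valTrace <- numeric(0)
    for (s in seq_len(steps)) {
      idx <- sample(trainIdx, min(batchSize, length(trainIdx)),
                    replace = length(trainIdx) < batchSize)
      grads <- NULL
      bl <- 0
      for (i in idx) {
        fw <- modelForward(model, pairs[[i]], train = TRUE, keepCache = TRUE)
        err <- fw$output - targets[i, ]
        bl <- bl + mean(err^2)
        g <- modelBackward(model, fw$cache, 2 * err / length(err))
        grads <- if (is.null(grads)) g else addTree(grads, g)
      }
      grads <- scaleTree(grads, 1 / length(idx))
      upd <- adamStep(opt, model@params, grads, lr)
      model@params <- upd$params; opt <- upd$state
      lossTrace <- c(lossTrace, bl / length(idx))
      if (length(valIdx) && (s %% evalEvery == 0L || s == steps)) {
        vl <- evalLoss(model, valIdx)
        valTrace <- c(valTrace, vl)
        if (vl < best$val) best <- list(params = model@params, val = vl)
      }
    }
    if (length(valIdx) && is.finite(best$val)) model@params <- best$params
    list(model = model, loss = lossTrace, valLoss = valTrace)
  })
}

pooledVector <- function(model, pair) {
  modelForward(model, pair, keepCache = TRUE)$cache$pooled
}

#' Stage-2 classification fine-tuning
#'
#' Swaps the head to classification, freezes everything else, and trains the
#' head only on the low-noise subset with balanced (50/50 expected) class
#' sampling and a binary cross-entropy loss. Because the backbone is frozen,
#' its pooled outputs are precomputed once and only the head is optimised;
#' all non-head parameters remain bit-identical.
#'
#' @param model a stage-1 trained [DualStreamModel-class]
#' @param pairs list of [PairTensors-class] for the low-noise records
#' @param labels logical success labels for the same records
#' @param steps,batchSize,lr optimisation controls
#' @param l2 weight decay on the head weights; the positive class is small,
#'   so the head needs explicit shrinkage to generalise across racemates
#' @param seed sampling / head-init seed
#' @return list with `model` (classifier) and `loss` trace
#' @export
stage2Finetune <- function(model, pairs, labels, steps = 300L, batchSize = 32L,
                           lr = 1e-2, l2 = 3e-3, seed = 1L) {
  checkPairsComplete(pairs)
  labels <- as.logical(labels)
  if (all(labels) || !any(labels))
    stop("fine-tuning subset must contain both classes", call. = FALSE)
  model <- swapHead(model, "classification", seed = seed)
  P <- do.call(rbind, lapply(pairs, function(p) pooledVector(model, p)))
  y <- as.numeric(labels)
  withSeed(seed + 1L, {
    head <- model@params$head
    opt <- adamInit(head)
    lossTrace <- numeric(0)
    for (s in seq_len(steps)) {
      idx <- sampleBalancedIndices(labels, batchSize)
      Pb <- P[idx, , drop = FALSE]
      yb <- y[idx]
      h <- pmax(addRows(Pb %*% head$W1, head$b1), 0)
      logit <- as.numeric(h %*% head$W2 + head$b2[1])
      prob <- 1 / (1 + exp(-logit))
      loss <- -mean(yb * log(pmax(prob, 1e-12)) +
                      (1 - yb) * log(pmax(1 - prob, 1e-12)))
      dlogit <- matrix((prob - yb) / length(yb), ncol = 1)
      g <- list(W1 = NULL, b1 = NULL,
                W2 = crossprod(h, dlogit) + l2 * head$W2,
                b2 = colSums(dlogit))
      dh <- tcrossprod(dlogit, head$W2) * (h > 0)
      g$W1 <- crossprod(Pb, dh) + l2 * head$W1
      g$b1 <- colSums(dh)
      upd <- adamStep(opt, head, g[names(head)], lr)
      head <- upd$params; opt <- upd$state
      lossTrace <- c(lossTrace, loss)
    }
    model@params$head <- head
    list(model = model, loss = lossTrace)
  })
}

#' Enrichment-factor curve of a ranked screen
#'
#' Records are ranked by descending score (ties broken by stable input
#' order); `EF(n)` is the number of hits in the top n divided by the number
#' expected under random sampling, `n H / N`. `EF(N) = 1` by construction.
#'
#' @param scores numeric scores
#' @param labels logical hit labels
#' @param at integer vector of n values (default all of 1..N)
#' @return data.frame with `n`, `hits`, `ef`
#' @export
enrichmentCurve <- function(scores, labels, at = NULL) {
  stopifnot(length(scores) == length(labels))
  N <- length(scores)
  H <- sum(labels)
  if (H == 0L) stop("enrichment factor undefined with zero hits", call. = FALSE)
  ord <- order(-scores)            # stable for ties
  cum <- cumsum(labels[ord])
  if (is.null(at)) at <- seq_len(N)
  data.frame(n = at, hits = cum[at], ef = cum[at] / (at * H / N))
}

#' Average precision of a ranked screen
#'
#' Standard step-integrated area under the precision-recall curve:
#' the mean over hits of the precision at each hit's rank, with descending
#' score order and stable tie-breaking.
#'
#' @param scores numeric scores
#' @param labels logical hit labels
#' @return scalar average precision
#' @export
averagePrecision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  H <- sum(labels)
  if (H == 0L) stop("average precision undefined with zero hits", call. = FALSE)
  ord <- order(-scores)
  lab <- labels[ord]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab]) / H
}

#' Train a two-stage ensemble on one training split
#'
#' For each member seed: initialise, stage-1 regression pre-training on all
#' training records, stage-2 classification fine-tuning on the low-noise
#' subset.
#'
#' @param pairs list of [PairTensors-class] (training records)
#' @param records labelled training records (see [labelRecords()])
#' @param modelCfg base [modelConfig()] (head kind regression)
#' @param nMembers ensemble size
#' @param seed base seed; member m uses `seed + m`
#' @param stage1 list of overrides for [stage1Train()] controls
#' @param stage2 list of overrides for [stage2Finetune()] controls
#' @param stage1Target `"m_frac_ee"` (two regression targets) or `"z"`
#' @return list of classifier models
#' @export
trainTwoStageEnsemble <- function(pairs, records, modelCfg, nMembers = 3L,
                                  seed = 1L, stage1 = list(), stage2 = list(),
                                  stage1Target = "m_frac_ee") {
  records <- labelRecords(records)
  targets <- stage1Targets(records, stage1Target)
  low <- which(records$low_noise)
  lapply(seq_len(nMembers), function(m) {
    cfg <- modelCfg
    cfg$seed <- seed + m
    cfg$n_outputs <- ncol(targets)
    model <- initModel(cfg)
    s1 <- do.call(stage1Train, c(list(model = model, pairs = pairs,
                                      targets = targets,
                                      seed = seed + 100L * m,
                                      racemates = records$racemate_id),
                                 stage1))
    s2 <- do.call(stage2Finetune, c(list(model = s1$model,
                                         pairs = pairs[low],
                                         labels = records$retrospective_hit[low],
                                         seed = seed + 200L * m),
                                    stage2))
    s2$model
  })
}

#' Score records with an ensemble
#' @param models list of classifier models
#' @param pairs list of [PairTensors-class]
#' @return numeric mean probabilities
#' @export
scoreRecords <- function(models, pairs) {
  vapply(pairs, function(p) ensemblePredict(models, p)$mean, numeric(1))
}

#' Learning curve over nested training subsets
#'
#' Training racemates are shuffled once; the subset for fraction f consists
#' of the first racemates (in that order) whose records reach f of the
#' training set, so smaller subsets are contained in larger ones. Each
#' subset trains an ensemble whose mean and standard deviation of average
#' precision on the fixed test records are reported. Fractions whose subset
#' contains fewer than one hit (or one class only) are skipped with a
#' warning.
#'
#' @param trainRecords,trainPairs training records and tensors
#' @param testRecords,testPairs fixed evaluation records and tensors
#' @param fractions increasing training fractions in (0, 1]
#' @param ensembleSize members per fraction
#' @param seed base seed
#' @param modelCfg base [modelConfig()]
#' @param stage1,stage2 control overrides, as in [trainTwoStageEnsemble()]
#' @return data.frame with `fraction`, `n_train`, `mean_ap`, `sd_ap`
#' @export
learningCurve <- function(trainRecords, trainPairs, testRecords, testPairs,
                          fractions = c(0.25, 0.5, 1.0), ensembleSize = 10L,
                          seed = 1L, modelCfg = modelConfig(),
                          stage1 = list(), stage2 = list()) {
  trainRecords <- labelRecords(trainRecords)
  testRecords <- labelRecords(testRecords)
  rac <- unique(trainRecords$racemate_id)
  ord <- withSeed(seed, sample(rac))
  nrec <- nrow(trainRecords)
  rows <- lapply(sort(fractions), function(f) {
    cum <- cumsum(table(factor(trainRecords$racemate_id, levels = ord))[ord])
    take <- ord[seq_len(which(cum >= f * nrec)[1])]
    idx <- which(trainRecords$racemate_id %in% take)
    sub <- trainRecords[idx, , drop = FALSE]
    low <- sub[sub$low_noise, , drop = FALSE]
    if (sum(low$retrospective_hit) < 1L || all(low$retrospective_hit)) {
      warning("fraction ", f, " skipped: training subset lacks a class")
      return(NULL)
    }
    models <- trainTwoStageEnsemble(trainPairs[idx], sub, modelCfg,
                                    nMembers = ensembleSize,
                                    seed = seed + round(1000 * f),
                                    stage1 = stage1, stage2 = stage2)
    aps <- vapply(models, function(m) {
      averagePrecision(vapply(testPairs, function(p) predictPair(m, p), numeric(1)),
                       testRecords$retrospective_hit)
    }, numeric(1))
    data.frame(fraction = f, n_train = length(idx),
               mean_ap = mean(aps), sd_ap = stats::sd(aps))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Rank resolving agents for a racemate
#'
#' Each agent's score is the maximum ensemble probability across all solvent
#' systems; agents are sorted descending with stable tie-breaking by agent
#' id.
#'
#' @param models ensemble of classifier models
#' @param pairs list of [PairTensors-class] for the agent x solvent grid
#' @param agentIds,solventIds character vectors aligned with `pairs`
#' @return data.frame with `agent_id`, `score`, `best_solvent`, sorted
#' @export
rankAgents <- function(models, pairs, agentIds, solventIds) {
  if (!length(pairs)) stop("empty agent x solvent grid", call. = FALSE)
  stopifnot(length(pairs) == length(agentIds),
            length(pairs) == length(solventIds))
  prob <- scoreRecords(models, pairs)
  agents <- unique(agentIds)
  rows <- lapply(agents, function(a) {
    sel <- which(agentIds == a)
    best <- sel[which.max(prob[sel])]
    data.frame(agent_id = a, score = prob[best],
               best_solvent = solventIds[best], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$score, out$agent_id), , drop = FALSE]
}
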