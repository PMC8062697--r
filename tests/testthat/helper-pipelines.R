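# End-to-end pipeline runs shared across test files (computed once per
# session; several properties are asserted against the same run).

.pipelineCache <- new.env(parent = emptyenv())

.cachedRun <- function(key, expr) {
  if (!exists(key, envir = .pipelineCache))
    assign(key, force(expr), envir = .pipelineCache)
  get(key, envir = .pipelineCache)
}

# Full multiplex pipeline on the standard SBM fixture (n=300, L=3, 2 equal
# blocks, pIn=0.1, pOut=0.01): split -> RWR-M -> truncate -> NCE training ->
# hadamard features -> logistic regressor.
standardPipelineRun <- function() .cachedRun("standard", {
  g <- generateMultiplexSBM(sbmSpec(), seed = 42)
  split <- splitMultiplex(g$network, 0.3, seed = 7)
  sim <- rwrSimilarity(split$train)
  cfg <- trainConfig(nNodes(g$network), seed = 11)
  trunc <- truncateSimilarity(sim, cfg$nMax)
  W0 <- initEmbeddings(cfg$nTotal, cfg$d, seed = cfg$seed)
  W <- trainEmbeddings(trunc, cfg)
  set.seed(99)
  Wshuf <- W[sample(nrow(W)), ]
  rownames(Wshuf) <- rownames(W)
  list(g = g, split = split, sim = sim, cfg = cfg, trunc = trunc,
       W0 = W0, W = W,
       auc = linkPrediction(W, split, "hadamard")$value,
       aucShuffled = linkPrediction(Wshuf, split, "hadamard")$value,
       lossInit = nceProbeLoss(trunc, W0, cfg),
       lossFinal = nceProbeLoss(trunc, W, cfg),
       klInit = klDivergence(sim, W0),
       klFinal = klDivergence(sim, W))
})

# Trainer quality-property fixture: same geometry (300 nodes, 3 layers,
# 2 equal blocks) with a strongly assortative, identifiable planted signal.
trainerQualityRun <- function() .cachedRun("quality", {
  g <- generateMultiplexSBM(sbmSpec(n = 300, L = 3, blocks = c(150, 150),
                                    pIn = 0.35, pOut = 0.002), seed = 42)
  split <- splitMultiplex(g$network, 0.3, seed = 7)
  W <- embedNodes(split$train, config = trainConfig(300, seed = 11))
  set.seed(99)
  Wshuf <- W[sample(nrow(W)), ]
  rownames(Wshuf) <- rownames(W)
  list(g = g, split = split, W = W,
       auc = linkPrediction(W, split, "hadamard")$value,
       aucShuffled = linkPrediction(Wshuf, split, "hadamard")$value)
})

# Multiplex-heterogeneous fixture: two 150-node 2-layer SBMs with 5 aligned
# blocks of 30 and community-aligned bipartite edges.
mhFixtureSpec <- function() sbmSpec(n = 150, L = 2, blocks = rep(30L, 5),
                                    pIn = 0.2, pOut = 0.01)

mhPipelineRun <- function() .cachedRun("mh", {
  mh <- generateMHSBM(mhFixtureSpec(), mhFixtureSpec(),
                      pBipIn = 0.2, pBipOut = 0.002, seed = 42)
  res <- suppressMessages(
    bipartiteLinkPrediction(mh$network, 0.3, "hadamard", seed = 11))
  list(mh = mh, res = res)
})
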