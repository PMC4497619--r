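# Shared fixture builders. All are generated in code at test time.

# a small random network on the toy schema, with association edges planted
# uniformly (no signal) so association-containing metapaths are populated
randomToyNet <- function(seed, nGene = 12, nDisease = 4, nTissue = 3,
                         nPathway = 4, density = 0.18, nPositives = 6,
                         distribution = "uniform") {
  mg <- toyMetagraph()
  net <- generateHetNet(
    mg,
    nodeCounts = c(Gene = nGene, Disease = nDisease, Tissue = nTissue,
                   Pathway = nPathway),
    edgeParams = list(
      GeT = list(density = density, distribution = distribution),
      DlT = list(density = 0.4),
      GiG = list(density = density / 2, distribution = distribution),
      GmPw = list(density = density)),
    seed = seed)
  planted <- plantAssociations(net, signalMetapaths = "GeTlD",
                               effectSize = 1, nPositives = nPositives,
                               predictionMetaedge = "DaG", seed = seed + 1)
  planted
}

# a planted-signal network: membership-sharing genes are far likelier to be
# associated with the same disease (set-traversing GmPwmGaD signal)
plantedSignalNet <- function(seed, nGene = 40, nDisease = 6, nPathway = 8,
                             nTissue = 4, effectSize = 12, nPositives = 40) {
  mg <- toyMetagraph()
  net <- generateHetNet(
    mg,
    nodeCounts = c(Gene = nGene, Disease = nDisease, Tissue = nTissue,
                   Pathway = nPathway),
    edgeParams = list(
      GeT = list(density = 0.15),
      DlT = list(density = 0.4),
      GiG = list(density = 0.05, distribution = "powerlaw"),
      GmPw = list(density = 0.12)),
    seed = seed)
  plantAssociations(net, signalMetapaths = "GmPwmGaD",
                    effectSize = effectSize, nPositives = nPositives,
                    predictionMetaedge = "DaG", seed = seed + 1)
}

toyMetaPath <- function(h, abbrev) parseMetaPath(metaGraph(h), abbrev)

# masked-edge set (package keys) and oracle masked data.frame for a pair's
# own association edge, if present
ownEdgeMask <- function(h, s, t, me = "DaG") {
  key <- edgeKey(h, s, t, me)
  eg <- edges(h)
  present <- key %in% paste(eg$source, eg$metaedge, eg$target, sep = "|")
  list(keys = if (present) key else character(0),
       df = if (present)
         data.frame(source = s, metaedge = me, target = t,
                    stringsAsFactors = FALSE)
       else data.frame(source = character(0), metaedge = character(0),
                       target = character(0)))
}
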