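# The three-pseudo-subject study used by the acceptance tests: ages 10, 15
# and 24 months, full 5-shell acquisition, reconstructed at every cumulative
# scheme with both models. Built once on first access and memoized.
studyCache <- local({
  cache <- NULL
  function(seed = 1) {
    if (!is.null(cache)) return(cache)
    sph <- testSphere()
    ages <- c(10, 15, 24)
    tab <- NULL
    recon <- list()
    phant <- list()
    for (i in seq_along(ages)) {
      spec <- phantomSpec(compartments = tissueCompartments(ages[i]),
                          ageMonths = ages[i], seed = seed + 1000L * i)
      ph <- buildPhantom(spec)
      phant[[i]] <- ph
      bm <- ph$truth$masks$bundle
      gm <- ph$truth$masks$gray
      for (k in 1:5) {
        sub <- selectSubset(ph$dwi, k)
        tf <- fitTensor(sub)
        sc <- tensorScalars(tf)
        odf <- frtODF(fitSH(sub), sph)
        g <- gfa(odf)
        pk <- findPeaks(odf)
        qn <- qaNQA(pk)
        recon[[paste(i, k)]] <- list(tensor = tf, peaks = pk,
                                     fa = sc$FA, nqa = qn$nqa)
        tab <- rbind(tab, data.frame(subject = i, age = ages[i], scheme = k,
          FA = mean(sc$FA@values[bm]), MD = mean(sc$MD@values[bm]),
          AX = mean(sc$AX@values[bm]), RD = mean(sc$RD@values[bm]),
          GFA = mean(g@values[bm]), NQA = mean(qn$nqa@values[bm]),
          grayFA = mean(sc$FA@values[gm]), grayGFA = mean(g@values[gm])))
      }
    }
    cache <<- list(tab = tab, recon = recon, phantoms = phant, ages = ages)
    cache
  }
})
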