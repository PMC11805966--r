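# Seven-variable forest-herb colonization model: two composite blocks,
# two single-indicator latents (reliability 0.9), saturated structural part.
observed: [text, mois, pH, age, dist, cover, colf]
blocks:
  - name: Soil
    components: [text, mois, pH]
  - name: Land
    components: [age, dist]
latents:
  - name: Comp
    indicator: cover
    reliability: 0.9
  - name: Colo
    indicator: colf
    reliability: 0.9
paths:
  - Soil -> Comp
  - Soil -> Colo
  - Land -> Comp
  - Land -> Colo
  - Comp -> Colo
covariances:
  - Soil ~~ Land
variant: free
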