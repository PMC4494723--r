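# First-pass extraction rule set for the 2013 Hattiesburg tornado setting.
# Broad by design: recall over precision; triangulation narrows afterwards.
keyword_terms:
  - tornado
  - storm
  - shelter
  - damage
  - relief
  - hattiesburg
  - mississippi
  - petal
hashtag_terms:
  - prayforhattiesburg
  - hattiesburg
  - mstornado
  - hburgstrong
  - tornado
bio_location_terms:
  - mississippi
  - alabama
  - hattiesburg
  - birmingham
  - petal
news_handles:
  - wdam
  - wlox
  - wjtv
  - wapt
  - wlbt
  - clarionledger
  - hattiesburgamer
  - wbrc
  - waff
gps_region:
  - MS
  - AL
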