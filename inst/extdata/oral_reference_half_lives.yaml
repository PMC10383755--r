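# Oral plasma half-lives of emtricitabine used as denominators for
# half-life-extension fold ratios. Values are literature references for
# conventional oral dosing in each species.
species:
  rat:
    t_half_h: 4.79
    note: oral FTC plasma half-life in rats (literature reference)
  mouse:
    t_half_h: 5.6
    note: oral FTC plasma half-life in mice (literature reference)
  human:
    t_half_h: 10
    note: >
      approximate oral FTC plasma half-life in humans; reported values range
      from ~7.4 h upward depending on study
# No published oral FTC pharmacokinetics are available in rabbits; the
# rabbit species therefore has no reference entry and no ratio is reported.
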