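<svg xmlns="http://www.w3.org/2000/svg" width="560" height="420" viewBox="0 0 560 420">
  <style>
    text { font-family: sans-serif; font-size: 13px; }
    .node { font-weight: bold; font-size: 15px; }
    .edge { stroke: #555; stroke-width: 1.4; fill: none; marker-end: url(#arr); }
    .weight { fill: #b30000; font-weight: bold; }
    .weight.zero { fill: #bbbbbb; }
    .fname { fill: #333; font-size: 11px; }
  </style>
  <defs>
    <marker id="arr" markerWidth="8" markerHeight="8" refX="7" refY="3" orient="auto">
      <path d="M0,0 L7,3 L0,6 z" fill="#555"/>
    </marker>
  </defs>
  <text class="node" x="60" y="60">Organic C</text>
  <text class="node" x="430" y="60">CO2</text>
  <text class="node" x="250" y="230">Acetate</text>
  <text class="node" x="60" y="230">Ethanol</text>
  <text class="node" x="430" y="360">CH4</text>
  <text class="node" x="60" y="360">H2</text>
  <path class="edge" d="M140,55 L420,55"/>
  <text class="fname" x="210" y="40">organic carbon oxidation</text>
  <text class="{{organic_carbon_oxidation_w.class}}" x="250" y="70">{{organic_carbon_oxidation_w.label}}</text>
  <path class="edge" d="M100,70 L240,220"/>
  <text class="fname" x="105" y="140">fermentation</text>
  <text class="{{fermentation_w.class}}" x="130" y="160">{{fermentation_w.label}}</text>
  <path class="edge" d="M110,225 L240,225"/>
  <text class="fname" x="125" y="210">ethanol oxidation</text>
  <text class="{{ethanol_oxidation_w.class}}" x="150" y="245">{{ethanol_oxidation_w.label}}</text>
  <path class="edge" d="M440,75 C420,160 360,200 310,220"/>
  <text class="fname" x="355" y="150">acetogenesis (WL)</text>
  <text class="{{acetogenesis_wl_w.class}}" x="365" y="170">{{acetogenesis_wl_w.label}}</text>
  <path class="edge" d="M310,235 C380,235 430,140 445,80"/>
  <text class="fname" x="400" y="255">acetate oxidation</text>
  <text class="{{acetate_oxidation_w.class}}" x="420" y="275">{{acetate_oxidation_w.label}}</text>
  <path class="edge" d="M450,75 L450,345"/>
  <text class="fname" x="458" y="210">methanogenesis</text>
  <text class="{{methanogenesis_w.class}}" x="458" y="230">{{methanogenesis_w.label}}</text>
  <path class="edge" d="M80,75 L70,345"/>
  <text class="fname" x="8" y="300">hydrogen generation</text>
  <text class="{{hydrogen_generation_w.class}}" x="20" y="320">{{hydrogen_generation_w.label}}</text>
  <path class="edge" d="M100,365 L300,400"/>
  <text class="fname" x="140" y="395">hydrogen oxidation</text>
  <text class="{{hydrogen_oxidation_w.class}}" x="180" y="415">{{hydrogen_oxidation_w.label}}</text>
</svg>
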