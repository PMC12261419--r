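<svg xmlns="http://www.w3.org/2000/svg" width="460" height="300" viewBox="0 0 460 300">
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
  <text class="node" x="60" y="150">SO4 2-</text>
  <text class="node" x="350" y="150">H2S</text>
  <path class="edge" d="M130,130 C220,70 280,70 345,130"/>
  <text class="fname" x="190" y="75">sulfate reduction</text>
  <text class="{{sulfate_reduction_w.class}}" x="215" y="95">{{sulfate_reduction_w.label}}</text>
  <path class="edge" d="M345,170 C280,230 200,230 125,170"/>
  <text class="fname" x="195" y="250">sulfur oxidation</text>
  <text class="{{sulfur_oxidation_w.class}}" x="215" y="230">{{sulfur_oxidation_w.label}}</text>
</svg>
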