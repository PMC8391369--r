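<?xml version="1.0" encoding="UTF-8"?>
<aiml version="subset-1" language="es">
<topic name="leave_conversation" description="farewell phrases closing the session">
  <category trigger="true">
    <pattern>adiós</pattern>
    <template><random><li>Hasta pronto. Me dio mucho gusto platicar contigo.</li><li>Adiós. Cuídate mucho y que tengas un bonito día.</li></random></template>
  </category>
  <category trigger="true">
    <pattern>adiós *</pattern>
    <template><srai>adiós</srai></template>
  </category>
  <category trigger="true">
    <pattern>* adiós</pattern>
    <template><srai>adiós</srai></template>
  </category>
  <category trigger="true">
    <pattern>* adiós *</pattern>
    <template><srai>adiós</srai></template>
  </category>
  <category trigger="true">
    <pattern>adios</pattern>
    <template><srai>adiós</srai></template>
  </category>
  <category trigger="true">
    <pattern>adios *</pattern>
    <template><srai>adiós</srai></template>
  </category>
  <category trigger="true">
    <pattern>* adios</pattern>
    <template><srai>adiós</srai></template>
  </category>
  <category trigger="true">
    <pattern>* adios *</pattern>
    <template><srai>adiós</srai></template>
  </category>
  <category trigger="true">
    <pattern>hasta luego</pattern>
    <template><srai>adiós</srai></template>
  </category>
  <category trigger="true">
    <pattern>* hasta luego</pattern>
    <template><srai>adiós</srai></template>
  </category>
  <category trigger="true">
    <pattern>hasta luego *</pattern>
    <template><srai>adiós</srai></template>
  </category>
  <category trigger="true">
    <pattern>me quiero ir</pattern>
    <template><srai>adiós</srai></template>
  </category>
  <category trigger="true">
    <pattern>* me quiero ir</pattern>
    <template><srai>adiós</srai></template>
  </category>
  <category trigger="true">
    <pattern>ya me voy</pattern>
    <template><srai>adiós</srai></template>
  </category>
  <category trigger="true">
    <pattern>* ya me voy</pattern>
    <template><srai>adiós</srai></template>
  </category>
</topic>
</aiml>
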